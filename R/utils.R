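# internal helpers shared across modules

`%||%` <- function(a, b) if (is.null(a)) b else a

# run expr under a fixed RNG seed without disturbing the caller's RNG state;
# seed = NULL leaves the current stream untouched
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  stopifnot(is.numeric(seed), length(seed) == 1, is.finite(seed))
  withr::with_seed(as.integer(seed), expr)
}

stop_if_not_scalar_prob <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1 || is.na(x) || x < 0 || x > 1)
    stop(sprintf("`%s` must be a single probability in [0, 1]", name), call. = FALSE)
}

# defect classes used throughout; "mixed" only ever appears as a consensus class
DEFECT_CLASSES <- c("swelling", "delamination_blebbing", "vesicle")

assert_defect_class <- function(x) {
  bad <- setdiff(unique(x), DEFECT_CLASSES)
  if (length(bad))
    stop("unknown defect class: ", paste(bad, collapse = ", "), call. = FALSE)
  invisible(x)
}
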