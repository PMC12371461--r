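# Generators: determinism, truth conservation, construction-level checks.

test_that("empty fiber list with zero noise renders an all-zero stack", {
  out <- render_brm_stack(list(), shape = c(64, 64, 5), seed = 1)
  expect_equal(out$stack, array(0, dim = c(64, 64, 5)))
  expect_equal(nrow(out$truth), 0)
})

test_that("a vesicle is visible in exactly its z_span planes", {
  ves <- defect_spec("vesicle", center = c(90, 45, 5), extent = c(4, 4),
                     z_span = 1)
  f <- straight_fiber(30, defects = list(ves))
  out <- render_brm_stack(list(f), shape = c(192, 192, 10), pixel_pitch = 1,
                          seed = 2)
  # the ring lives around (90, 45), far from the fiber lines at y = 29/31
  roi <- out$stack[40:50, 85:95, ]
  expect_gt(max(roi[, , 5]), 0.5)
  for (k in setdiff(1:10, 5)) expect_equal(max(roi[, , k]), 0)

  ves2 <- defect_spec("vesicle", center = c(90, 45, 5), extent = c(4, 4),
                      z_span = 2)
  f2 <- straight_fiber(30, defects = list(ves2))
  out2 <- render_brm_stack(list(f2), shape = c(192, 192, 10), pixel_pitch = 1)
  roi2 <- out2$stack[40:50, 85:95, ]
  expect_gt(min(max(roi2[, , 5]), max(roi2[, , 6])), 0.5)
  for (k in setdiff(1:10, 5:6)) expect_equal(max(roi2[, , k]), 0)
})

test_that("vesicles with z_span > 2 are rejected", {
  expect_error(defect_spec("vesicle", c(10, 10, 3), c(4, 4), z_span = 3),
               "1 or 2")
})

test_that("defects outside the stack bounds are rejected with a clear error", {
  bad <- defect_spec("swelling", center = c(500, 30, 5), extent = c(5, 5))
  f <- straight_fiber(30, defects = list(bad))
  expect_error(render_brm_stack(list(f), shape = c(192, 192, 10),
                                pixel_pitch = 1),
               "outside stack bounds")
  bad_z <- defect_spec("swelling", center = c(90, 30, 10), extent = c(5, 5),
                       z_span = 3)
  expect_error(render_brm_stack(list(straight_fiber(30, defects = list(bad_z))),
                                shape = c(192, 192, 10), pixel_pitch = 1),
               "outside stack bounds")
})

test_that("truth list is conserved and matches an independent blob re-detection", {
  # 20 vesicles on an invisible fiber, spaced out; re-detect them as
  # connected bright components with EBImage (independent of the renderer)
  centers <- expand.grid(x = seq(30, 270, by = 60), y = seq(30, 210, by = 60))
  centers <- centers[1:20, ]
  defs <- lapply(seq_len(20), function(i)
    defect_spec("vesicle", c(centers$x[i], centers$y[i], 3), c(6, 6)))
  f <- fiber_spec(rbind(c(1, 1), c(2, 1)), intensity = 0, defects = defs)
  out <- render_brm_stack(list(f), shape = c(240, 300, 5), pixel_pitch = 1,
                          seed = 3)
  expect_equal(nrow(out$truth), 20)
  proj <- apply(out$stack, c(1, 2), max)
  lab <- EBImage::bwlabel(proj > 0.3)
  expect_equal(max(lab), 20)
})

test_that("identical seeds give bit-identical generator output", {
  f <- straight_fiber(30, defects = list(
    defect_spec("delamination_blebbing", c(60, 30, 2), c(8, 6), z_span = 2)))
  a <- render_brm_stack(list(f), c(96, 192, 4), pixel_pitch = 1,
                        noise_sd = 0.1, seed = 11)
  b <- render_brm_stack(list(f), c(96, 192, 4), pixel_pitch = 1,
                        noise_sd = 0.1, seed = 11)
  expect_identical(a, b)

  truth <- grid_truth(30)
  m <- annotator_model(sensitivity = 0.7, jitter_sd = 2,
                       false_positive_rate = 1)
  expect_identical(simulate_annotations(truth, m, seed = 5),
                   simulate_annotations(truth, m, seed = 5))

  expect_identical(render_stain_image(c(50, 50), 0.4, seed = 9),
                   render_stain_image(c(50, 50), 0.4, seed = 9))
  expect_identical(generate_cohort(cohort_spec(), seed = 13),
                   generate_cohort(cohort_spec(), seed = 13))
  v1 <- simulate_psoct_volume(matrix(0.3, 3, 3), 10, noise_sd = 0.1, seed = 17)
  v2 <- simulate_psoct_volume(matrix(0.3, 3, 3), 10, noise_sd = 0.1, seed = 17)
  expect_identical(v1, v2)
})

test_that("perfect annotators reproduce the truth exactly; blind ones nothing", {
  truth <- grid_truth(7)
  perfect <- annotator_model(sensitivity = 1, jitter_sd = 0,
                             false_positive_rate = 0)
  ann <- simulate_annotations(truth, perfect, n_annotators = 3, seed = 1)
  for (a in c("A1", "A2", "A3")) {
    got <- ann[ann$annotator_id == a, c("x", "y", "w", "h", "z", "class")]
    rownames(got) <- NULL
    expect_equal(got, truth[, c("x", "y", "w", "h", "z", "class")])
  }
  blind <- annotator_model(sensitivity = 0, false_positive_rate = 0)
  expect_equal(nrow(simulate_annotations(truth, blind, seed = 1)), 0)
})

test_that("class confusion draws reported classes at the specified rates", {
  conf <- matrix(c(0.6, 0.3, 0.1,
                   0, 1, 0,
                   0, 0, 1), 3, 3, byrow = TRUE)
  truth <- grid_truth(600, classes = rep("swelling", 600), ncol_grid = 25)
  ann <- simulate_annotations(truth, annotator_model(1, 0, conf, 0),
                              n_annotators = 1, seed = 21)
  freq <- table(factor(ann$class, levels = c("swelling",
                                             "delamination_blebbing",
                                             "vesicle"))) / 600
  expect_equal(as.numeric(freq), c(0.6, 0.3, 0.1), tolerance = 0.08)
})

test_that("stain generator hits the requested positive fraction and limits", {
  z <- render_stain_image(c(60, 60), 0, seed = 1)
  expect_false(any(z$mask))
  expect_equal(z$positive_fraction, 0)
  o <- render_stain_image(c(60, 60), 1, seed = 1)
  expect_true(all(o$mask))
  h <- render_stain_image(c(100, 100), 0.30, seed = 4)
  expect_equal(mean(h$mask), 0.30, tolerance = 5e-3)
})

test_that("cohort generator honours sizes and the degenerate noiseless case", {
  spec0 <- cohort_spec(group_effects = c(NC = 0, CTE = 0, AD = 0),
                       age_effect = 0, subject_sd = 0, residual_sd = 0)
  tab <- generate_cohort(spec0, seed = 2)
  expect_equal(length(unique(tab$subject_id)), 14)
  expect_equal(nrow(tab), 14 * spec0$measurements_per_subject)
  expect_true(all(tab$density == spec0$baseline_density))
  expect_equal(as.vector(table(tab$group)[c("NC", "CTE", "AD")]) /
                 spec0$measurements_per_subject, c(4, 5, 5))
})

test_that("age-confounded contrast is biased by age_effect * group age gap", {
  # pure age effect, zero group effects: the naive CTE - NC contrast should
  # average age_effect * (mean CTE age - mean NC age); subtracting the
  # generating age term removes the bias
  spec <- cohort_spec(age_effect = 0.5, subject_sd = 0, residual_sd = 0,
                      measurements_per_subject = 1L)
  expected <- 0.5 * (spec$age_mean["CTE"] - spec$age_mean["NC"])
  naive <- adj <- numeric(200)
  withr::with_seed(31, {
    for (r in 1:200) {
      tab <- generate_cohort(spec)
      age_term <- 0.5 * (tab$age_years - mean(tab$age_years))
      naive[r] <- mean(tab$density[tab$group == "CTE"]) -
        mean(tab$density[tab$group == "NC"])
      d_adj <- tab$density - age_term
      adj[r] <- mean(d_adj[tab$group == "CTE"]) - mean(d_adj[tab$group == "NC"])
    }
  })
  se <- sd(naive) / sqrt(200)
  expect_lt(abs(mean(naive) - expected), 3 * se)
  expect_lt(abs(mean(adj)), 1e-8)
})
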