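subject_id,group,sex,age_years,pmi_hours,stage,cds,cdr
S01,NC,F,61,4,,,
S02,NC,M,69,13.5,,,
S03,NC,M,67,13.5,,,
S04,NC,M,59,13.92,,,
S05,CTE,M,81,15.75,III,122,
S06,CTE,M,89,17.5,III,156,
S07,CTE,M,78,7,IV,156,
S08,CTE,M,75,16.5,IV,147,
S09,CTE,M,86,18.75,III,65,
S10,AD,F,84,6.5,VI,,3
S11,AD,M,76,3,VI,,2
S12,AD,M,86,6.25,VI,,2
S13,AD,F,83,10.5,VI,,3
S14,AD,M,65,17.75,VI,153,
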