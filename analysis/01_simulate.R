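#!/usr/bin/env Rscript
# Stage 1 — simulate the study cohort.
#
# The study data are private, so the whole analysis runs on a synthetic
# cohort with three planted phenogroups (Table-3-like profiles),
# exponential survival with hazards 1 : 1.618 : 2.632, a CRT-D benefit
# (HR 0.454) planted in the high-risk group only, 10-year
# administrative censoring and MCAR missingness in the lab/echo
# features.

library(crtphenomap)

out_dir <- "results/analysis"
dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

cfg <- sim_config(n_patients = 1000, seed = 20260101)
sc <- generate_cohort(cfg)
print(sc)

write_cohort_csv(sc,
                 cohort_file = file.path(out_dir, "cohort.csv"),
                 labels_file = file.path(out_dir, "latent_labels.csv"))

# descriptive per-group feature profile (the analogue of a Table 1/3)
profile <- do.call(rbind, lapply(tda_features, function(f) {
  v <- sc$cohort[[f]]
  data.frame(feature = f,
             t(tapply(v, sc$latent_group, function(z) {
               round(mean(z, na.rm = TRUE), 3)
             })))
}))
write.csv(profile, file.path(out_dir, "planted_profiles.csv"),
          row.names = FALSE)
message("cohort written: ", nrow(sc$cohort), " patients, ",
        sum(sc$cohort$event), " deaths")
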