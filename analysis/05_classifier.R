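#!/usr/bin/env Rscript
# Stage 5 — nested cross-validated classifier ensemble.
#
# The phenogroup labels from stage 3 are learned from the 16 raw
# features with a 5x5 nested cross-validation (inner loop: grid search
# by balanced accuracy over five model families; outer loop: one
# evaluation per tuned model), yielding an ensemble of 5 classifiers
# for new patients.

library(crtphenomap)

out_dir <- "results/analysis"
cohort <- read_cohort_csv(file.path(out_dir, "cohort.csv"))
run <- run_phenomap(cohort)

asg <- run$assignment
keep <- !is.na(asg$phenogroup)
x <- encode_features(cohort)[keep, ]
y <- droplevels(asg$phenogroup[keep])

ens <- nested_cv_train(x, y, nested_cv_config(seed = 1))
print(ens)

jsonlite::write_json(
  list(aggregate = ens$metrics$aggregate,
       per_fold = ens$metrics$per_fold,
       selected_families = vapply(ens$members, `[[`, "", "family")),
  file.path(out_dir, "classifier_metrics.json"),
  auto_unbox = TRUE, digits = NA)
write.csv(as.data.frame(ens$metrics$confusion),
          file.path(out_dir, "confusion.csv"), row.names = FALSE)

# demonstrate prediction on new simulated patients
new_sc <- generate_cohort(sim_config(n_patients = 100, seed = 20260999))
pred <- predict_ensemble(ens, new_sc$cohort)
message("new-patient phenogroup assignments: ",
        paste(sprintf("%s=%d", levels(pred$class), table(pred$class)),
              collapse = ", "))
write.csv(
  data.frame(patient_id = new_sc$cohort$patient_id,
             phenogroup = pred$class, round(pred$prob, 4)),
  file.path(out_dir, "new_patient_predictions.csv"), row.names = FALSE)
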