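#!/usr/bin/env Rscript
# Stage 4 — survival analyses of the phenogroups.
#
# Kaplan-Meier curves per phenogroup (log-log CIs), k-group log-rank
# test, phenogroup hazard ratios vs the low-risk group, the device
# (CRT-D vs CRT-P) effect within each phenogroup, the clinical subgroup
# forest, and reverse-KM follow-up.

library(crtphenomap)

out_dir <- "results/analysis"
cohort <- read_cohort_csv(file.path(out_dir, "cohort.csv"))
run <- run_phenomap(cohort)

surv <- phenomap_survival(run, cohort)
print(surv$logrank)
print(surv$cox_phenogroup)
message(sprintf("median follow-up (reverse KM): %.2f years",
                surv$followup$median))

# KM plot per phenogroup
png(file.path(out_dir, "km_phenogroups.png"), 900, 700)
cols <- c(low = "forestgreen", intermediate = "orange", high = "firebrick")
plot(NULL, xlim = c(0, 10), ylim = c(0, 1), xlab = "Years since upgrade",
     ylab = "Survival probability",
     main = "Survival of the phenogroups (Kaplan-Meier)")
for (g in names(surv$km_by_group)) {
  km <- surv$km_by_group[[g]]
  lines(stepfun(km$time, c(1, km$surv)), do.points = FALSE, col = cols[g],
        lwd = 2)
}
legend("bottomleft", legend = names(cols), col = cols, lwd = 2)
dev.off()

# device effect within phenogroups + subgroup forest
asg <- run$assignment
keep <- !is.na(asg$phenogroup)
dat <- cohort[keep, ]
dat$phenogroup <- asg$phenogroup[keep]
forest <- subgroup_forest(dat)
write.csv(forest, file.path(out_dir, "subgroup_forest.csv"),
          row.names = FALSE)

png(file.path(out_dir, "forest.png"), 800, 900)
ok <- !is.na(forest$hr)
fp <- forest[ok, ]
y <- rev(seq_len(nrow(fp)))
plot(NULL, xlim = c(0.1, 4), ylim = range(y) + c(-1, 1), log = "x",
     yaxt = "n", xlab = "HR, CRT-D vs CRT-P", ylab = "",
     main = "Device effect by clinical subgroup")
abline(v = 1, lty = 2)
segments(fp$lower, y, fp$upper, y)
points(fp$hr, y, pch = 15)
axis(2, at = y, labels = paste(fp$variable, fp$stratum, sep = ": "),
     las = 1, cex.axis = 0.7)
dev.off()

for (g in names(surv$cox_device_by_group)) {
  f <- surv$cox_device_by_group[[g]]
  if (!is.null(f)) {
    message(sprintf("device HR in %s-risk group: %.3f (%.3f-%.3f)",
                    g, f$table$hr, f$table$lower, f$table$upper))
  }
}
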