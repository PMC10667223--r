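#' Canonical feature sets
#'
#' The 16 pre-upgrade clinical features used to build the topological
#' network, in canonical column order: age (years), male sex, implanted
#' device (CRT-D indicator), NYHA functional class III-IV, histories of
#' atrial fibrillation, hypertension, diabetes mellitus, ischemic HF
#' etiology, myocardial infarction, PCI and CABG, serum creatinine
#' (umol/L), GFR (mL/min/1.73m2), LVEF (%), and LV end-diastolic and
#' end-systolic diameters (mm).
#'
#' @format Character vectors of column names.
#' @export
tda_features <- c(
  "age", "male", "device_crtd", "nyha_34", "af", "hypertension", "dm",
  "ischemic_etiology", "mi", "pci", "cabg", "creatinine", "gfr", "lvef",
  "lvidd", "lvids"
)

#' @rdname tda_features
#' @export
tda_binary_features <- c(
  "male", "device_crtd", "nyha_34", "af", "hypertension", "dm",
  "ischemic_etiology", "mi", "pci", "cabg"
)

#' @rdname tda_features
#' @export
tda_continuous_features <- setdiff(tda_features, tda_binary_features)

group_levels <- c("low", "intermediate", "high")

#' Default per-phenogroup feature profiles
#'
#' Per-group generative parameters for each of the 16 features: Bernoulli
#' rates for binary indicators and truncated-Gaussian location/spread for
#' continuous features.  Values mirror the published phenogroup profiles
#' of a single-center CRT upgrade cohort (e.g. male 58/75/93%, ischemic
#' etiology 2/47/100% across the low/intermediate/high-risk groups);
#' spreads are IQR-derived.  They are stand-ins for testing the pipeline,
#' not estimates of any real cohort.
#'
#' @return Named list, one element per feature.  Binary features carry
#'   `rate` (length-3, low/intermediate/high); continuous features carry
#'   `mean`, `sd` and truncation `lower`/`upper`.
#' @export
default_feature_profiles <- function() {
  bin <- function(lo, mid, hi) {
    list(type = "binary", rate = c(low = lo, intermediate = mid, high = hi))
  }
  con <- function(m, s, lower, upper) {
    list(type = "continuous",
         mean = stats::setNames(m, group_levels),
         sd = stats::setNames(s, group_levels),
         lower = lower, upper = upper)
  }
  list(
    age = con(c(75.2, 73.8, 72.4), c(7.0, 9.6, 6.8), 40, 95),
    male = bin(0.58, 0.75, 0.93),
    # device_crtd is generated from device_assignment_rate_per_group
    nyha_34 = bin(0.40, 0.49, 0.53),
    af = bin(0.64, 0.50, 0.48),
    hypertension = bin(0.78, 0.75, 0.75),
    dm = bin(0.27, 0.39, 0.48),
    ischemic_etiology = bin(0.02, 0.47, 1.00),
    mi = bin(0.01, 0.36, 0.67),
    pci = bin(0.00, 0.33, 0.65),
    cabg = bin(0.01, 0.19, 0.30),
    creatinine = con(c(96, 119, 120), c(23, 44, 41), 30, 600),
    gfr = con(c(65, 53, 53), c(22, 27, 22), 5, 120),
    lvef = con(c(30, 30, 28), c(5.2, 7.4, 5.2), 10, 60),
    lvidd = con(c(59, 60, 64), c(5, 11, 7), 35, 90),
    lvids = con(c(48, 49, 54), c(5, 12, 7), 25, 85)
  )
}

#' Simulation configuration for synthetic CRT upgrade cohorts
#'
#' Defines a three-phenogroup generative model: group-specific feature
#' profiles, exponential (constant-hazard) survival with group baseline
#' hazards in the ratio 1 : 1.618 : 2.632, a CRT-D survival benefit
#' concentrated in the high-risk group (hazard ratio 0.454), independent
#' exponential non-death censoring (transplant / subsequent-upgrade
#' analogue), 10-year administrative censoring, and MCAR feature
#' missingness.
#'
#' @param n_patients Number of patients to simulate.
#' @param group_weights Length-3 probabilities (low, intermediate, high)
#'   summing to 1.
#' @param feature_profiles Per-group feature parameters, see
#'   [default_feature_profiles()].
#' @param baseline_hazard_per_group Death hazard (events/year) for the
#'   low/intermediate/high groups among CRT-P patients.
#' @param device_assignment_rate_per_group Probability of receiving a
#'   CRT-D (vs CRT-P) in each group.
#' @param device_log_hazard_per_group Log hazard ratio of CRT-D vs CRT-P
#'   within each group (default: effect only in the high-risk group,
#'   `log(0.454)`).
#' @param admin_censor_years Administrative censoring horizon (years).
#' @param competing_censor_rate Rate (events/year) of independent
#'   non-death censoring.
#' @param missing_rate_per_feature Named vector of MCAR missingness
#'   probabilities in `[0, 1)`; unnamed features default to 0.
#' @param seed Integer seed; cohorts are reproducible given the seed.
#' @return An object of class `sim_config`.
#' @export
sim_config <- function(n_patients = 1000,
                       group_weights = c(0.31, 0.37, 0.32),
                       feature_profiles = default_feature_profiles(),
                       baseline_hazard_per_group = 0.08 * c(1, 1.618, 2.632),
                       device_assignment_rate_per_group = c(0.46, 0.28, 0.35),
                       device_log_hazard_per_group = c(0, 0, log(0.454)),
                       admin_censor_years = 10,
                       competing_censor_rate = 0.005,
                       missing_rate_per_feature = c(
                         creatinine = 0.23, gfr = 0.23, lvef = 0.10,
                         lvidd = 0.14, lvids = 0.31
                       ),
                       seed = 1L) {
  cfg <- list(
    n_patients = n_patients,
    group_weights = stats::setNames(group_weights, group_levels),
    feature_profiles = feature_profiles,
    baseline_hazard_per_group =
      stats::setNames(baseline_hazard_per_group, group_levels),
    device_assignment_rate_per_group =
      stats::setNames(device_assignment_rate_per_group, group_levels),
    device_log_hazard_per_group =
      stats::setNames(device_log_hazard_per_group, group_levels),
    admin_censor_years = admin_censor_years,
    competing_censor_rate = competing_censor_rate,
    missing_rate_per_feature = missing_rate_per_feature,
    seed = as.integer(seed)
  )
  class(cfg) <- "sim_config"
  validate_sim_config(cfg)
  cfg
}

validate_sim_config <- function(cfg) {
  fail <- function(field, why) {
    stop("invalid simulation config: field `", field, "` ", why,
         call. = FALSE)
  }
  if (!is.numeric(cfg$n_patients) || length(cfg$n_patients) != 1 ||
      cfg$n_patients < 1 || cfg$n_patients != round(cfg$n_patients)) {
    fail("n_patients", "must be a positive integer")
  }
  if (length(cfg$group_weights) != 3 || any(cfg$group_weights < 0)) {
    fail("group_weights", "must be 3 non-negative probabilities")
  }
  if (abs(sum(cfg$group_weights) - 1) > 1e-12) {
    fail("group_weights", "must sum to 1")
  }
  if (length(cfg$baseline_hazard_per_group) != 3 ||
      any(cfg$baseline_hazard_per_group < 0)) {
    fail("baseline_hazard_per_group", "must be 3 non-negative rates")
  }
  if (length(cfg$device_assignment_rate_per_group) != 3 ||
      any(cfg$device_assignment_rate_per_group < 0) ||
      any(cfg$device_assignment_rate_per_group > 1)) {
    fail("device_assignment_rate_per_group", "must be 3 probabilities")
  }
  if (length(cfg$device_log_hazard_per_group) != 3 ||
      any(!is.finite(cfg$device_log_hazard_per_group))) {
    fail("device_log_hazard_per_group", "must be 3 finite log hazard ratios")
  }
  if (!is.numeric(cfg$admin_censor_years) || cfg$admin_censor_years <= 0) {
    fail("admin_censor_years", "must be > 0")
  }
  if (cfg$competing_censor_rate < 0) {
    fail("competing_censor_rate", "must be >= 0")
  }
  mr <- cfg$missing_rate_per_feature
  if (length(mr) && (is.null(names(mr)) ||
                     !all(names(mr) %in% setdiff(tda_features, "device_crtd")))) {
    fail("missing_rate_per_feature",
         "must be named after (non-device) features")
  }
  if (length(mr) && (any(mr < 0) || any(mr >= 1))) {
    fail("missing_rate_per_feature", "rates must lie in [0, 1)")
  }
  miss_prof <- setdiff(setdiff(tda_features, "device_crtd"),
                       names(cfg$feature_profiles))
  if (length(miss_prof)) {
    fail("feature_profiles",
         paste0("lacks entries for: ", paste(miss_prof, collapse = ", ")))
  }
  invisible(cfg)
}

# truncated normal via inverse-CDF; vectorised over n
rtruncnorm <- function(n, mean, sd, lower, upper) {
  p_lo <- stats::pnorm(lower, mean, sd)
  p_hi <- stats::pnorm(upper, mean, sd)
  stats::qnorm(stats::runif(n, p_lo, p_hi), mean, sd)
}

#' Generate a synthetic CRT upgrade cohort
#'
#' Draws latent phenogroups, group-conditional clinical features, an
#' exponential proportional-hazards survival time (hazard =
#' group baseline x exp(group device log-HR x CRT-D)), applies the
#' censoring rules (earliest of death, independent non-death censoring,
#' and the administrative horizon), then injects MCAR missingness into
#' the features.  Outcome fields are never missing.
#'
#' @param config A [sim_config()] object.
#' @return An object of class `synthetic_cohort`: a list with `cohort`
#'   (data frame: `patient_id`, the 16 features, `time_years`, `event`,
#'   `censor_reason`) and `latent_group` (factor, the planted group).
#' @export
generate_cohort <- function(config = sim_config()) {
  validate_sim_config(config)
  set.seed(config$seed)
  n <- config$n_patients
  g_idx <- sample.int(3, n, replace = TRUE, prob = config$group_weights)
  latent <- factor(group_levels[g_idx], levels = group_levels)

  cohort <- data.frame(patient_id = sprintf("P%05d", seq_len(n)))
  for (f in tda_features) {
    if (f == "device_crtd") {
      rate <- config$device_assignment_rate_per_group[g_idx]
      cohort[[f]] <- stats::rbinom(n, 1, rate)
    } else {
      prof <- config$feature_profiles[[f]]
      if (prof$type == "binary") {
        cohort[[f]] <- stats::rbinom(n, 1, prof$rate[g_idx])
      } else {
        cohort[[f]] <- rtruncnorm(n, prof$mean[g_idx], prof$sd[g_idx],
                                  prof$lower, prof$upper)
      }
    }
  }

  haz <- config$baseline_hazard_per_group[g_idx] *
    exp(config$device_log_hazard_per_group[g_idx] * cohort$device_crtd)
  t_death <- stats::rexp(n, haz)
  t_comp <- if (config$competing_censor_rate > 0) {
    stats::rexp(n, config$competing_censor_rate)
  } else {
    rep(Inf, n)
  }
  horizon <- config$admin_censor_years
  time <- pmin(t_death, t_comp, horizon)
  event <- as.integer(t_death <= pmin(t_comp, horizon))
  reason <- rep("none", n)
  comp_wins <- event == 0 & t_comp < horizon
  # non-death censoring mimics subsequent CRT-D upgrade (CRT-P patients)
  # or heart transplantation (CRT-D patients)
  reason[comp_wins & cohort$device_crtd == 0] <- "subsequent_upgrade"
  reason[comp_wins & cohort$device_crtd == 1] <- "transplant"
  reason[event == 0 & !comp_wins] <- "admin_10y"
  cohort$time_years <- time
  cohort$event <- event
  cohort$censor_reason <- factor(reason, levels = censor_reason_levels)

  mr <- config$missing_rate_per_feature
  for (f in names(mr)) {
    if (mr[[f]] > 0) {
      cohort[[f]][stats::runif(n) < mr[[f]]] <- NA
    }
  }

  structure(list(cohort = cohort, latent_group = latent, config = config),
            class = "synthetic_cohort")
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  cat("Synthetic CRT upgrade cohort:", nrow(x$cohort), "patients\n")
  cat("  planted groups:",
      paste(sprintf("%s=%d", levels(x$latent_group),
                    tabulate(x$latent_group, 3)), collapse = ", "), "\n")
  cat("  deaths:", sum(x$cohort$event), sprintf("(%.0f%%)",
      100 * mean(x$cohort$event)), "\n")
  invisible(x)
}

#' Closed-form survival of the planted generative model
#'
#' Survival probability `exp(-hazard * t)` of the planted exponential
#' death-time model, where hazard = group baseline x exp(group device
#' log-HR x device).  Serves as the analytic oracle for Kaplan-Meier
#' validation; censoring is not part of this curve.
#'
#' @param config A [sim_config()].
#' @param group One of `"low"`, `"intermediate"`, `"high"`.
#' @param device 0 (CRT-P) or 1 (CRT-D).
#' @param t Time(s) in years, non-negative.
#' @return Survival probabilities, same length as `t`.
#' @export
closed_form_survival <- function(config, group, device, t) {
  if (length(group) != 1 || !group %in% group_levels) {
    stop("unknown group label: ", paste(group, collapse = ", "),
         " (expected one of ", paste(group_levels, collapse = ", "), ")",
         call. = FALSE)
  }
  if (any(t < 0)) stop("t must be non-negative", call. = FALSE)
  h <- config$baseline_hazard_per_group[[group]] *
    exp(config$device_log_hazard_per_group[[group]] * device)
  exp(-h * t)
}

#' Write a synthetic cohort to CSV
#'
#' Writes the cohort table (schema of [encode_features()]) and,
#' separately, the latent planted labels (testing only).
#'
#' @param x A `synthetic_cohort`.
#' @param cohort_file,labels_file Output paths; `labels_file = NULL`
#'   skips the label file.
#' @export
write_cohort_csv <- function(x, cohort_file, labels_file = NULL) {
  utils::write.csv(x$cohort, cohort_file, row.names = FALSE)
  if (!is.null(labels_file)) {
    utils::write.csv(
      data.frame(patient_id = x$cohort$patient_id,
                 latent_group = as.character(x$latent_group)),
      labels_file, row.names = FALSE)
  }
  invisible(x)
}
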