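censor_reason_levels <- c("none", "admin_10y", "subsequent_upgrade",
                          "transplant", "query_date")

#' Apply the study censoring rules
#'
#' Follow-up runs from the upgrade procedure.  A patient is right
#' censored at the earliest of: (1) the administrative horizon (10
#' years), (2) a subsequent CRT-D upgrade after a CRT-P upgrade, (3)
#' heart transplantation, or (4) the data-query date if alive before
#' the horizon.  A death at or before the earliest censoring time is an
#' event; a death after it does not count.
#'
#' @param outcomes Data frame with per-patient times in years from the
#'   upgrade: `death_years`, and optionally `crtd_upgrade_years`,
#'   `transplant_years`, `query_years` (`NA` where not applicable;
#'   `query_years` defaults to the horizon).
#' @param horizon Administrative censoring horizon in years (default 10).
#' @return Data frame: `time_years`, `event` (0/1), `censor_reason`
#'   (factor: none, admin_10y, subsequent_upgrade, transplant,
#'   query_date).
#' @export
apply_censoring <- function(outcomes, horizon = 10) {
  n <- nrow(outcomes)
  get <- function(col, default = NA_real_) {
    if (col %in% names(outcomes)) as.numeric(outcomes[[col]])
    else rep(default, n)
  }
  death <- get("death_years")
  upg <- get("crtd_upgrade_years")
  htx <- get("transplant_years")
  query <- get("query_years", default = horizon)
  query[is.na(query)] <- horizon
  for (v in list(death, upg, htx, query)) {
    if (any(v < 0, na.rm = TRUE)) {
      stop("negative follow-up time (event before upgrade)", call. = FALSE)
    }
  }
  # candidate censor times, in rule priority order for exact ties
  cand <- cbind(admin_10y = rep(horizon, n), subsequent_upgrade = upg,
                transplant = htx, query_date = query)
  c_time <- apply(cand, 1, min, na.rm = TRUE)
  c_which <- apply(cand, 1, which.min)  # first minimum = priority order
  is_event <- !is.na(death) & death <= c_time
  data.frame(
    time_years = ifelse(is_event, death, c_time),
    event = as.integer(is_event),
    censor_reason = factor(
      ifelse(is_event, "none", colnames(cand)[c_which]),
      levels = censor_reason_levels))
}

#' Censoring from raw dates
#'
#' Convenience wrapper converting ISO-8601 dates to years from the
#' upgrade date (365.25-day years) before applying [apply_censoring()].
#'
#' @param upgrade_date,death_date,crtd_upgrade_date,transplant_date
#'   Vectors coercible with [as.Date()]; `NA` where not applicable.
#' @param query_date The data-query date (scalar or vector).
#' @param horizon Administrative horizon in years.
#' @return As [apply_censoring()].
#' @export
censor_from_dates <- function(upgrade_date, death_date = NA,
                              crtd_upgrade_date = NA, transplant_date = NA,
                              query_date, horizon = 10) {
  yrs <- function(d) {
    as.numeric(as.Date(d) - as.Date(upgrade_date)) / 365.25
  }
  n <- length(upgrade_date)
  rep_len2 <- function(x) rep_len(x, n)
  apply_censoring(data.frame(
    death_years = yrs(rep_len2(death_date)),
    crtd_upgrade_years = yrs(rep_len2(crtd_upgrade_date)),
    transplant_years = yrs(rep_len2(transplant_date)),
    query_years = yrs(rep_len2(query_date))), horizon = horizon)
}

#' Kaplan-Meier estimate
#'
#' Product-limit estimator with Greenwood variance and log-log 95%
#' confidence intervals.
#'
#' @param time Follow-up times (years), non-negative.
#' @param event 0/1 event indicators.
#' @param conf.level Confidence level (default 0.95).
#' @return An object of class `km_curve`: `time` (event times),
#'   `n_risk`, `n_event`, `surv`, `var` (Greenwood), `lower`, `upper`,
#'   `n`, `n_events`.
#' @export
km_estimate <- function(time, event, conf.level = 0.95) {
  stopifnot(length(time) == length(event), length(time) >= 1)
  if (any(time < 0)) stop("negative times", call. = FALSE)
  if (all(time == 0)) stop("all follow-up times are zero", call. = FALSE)
  ut <- sort(unique(time[event == 1]))
  n_risk <- vapply(ut, function(t) sum(time >= t), 0)
  n_event <- vapply(ut, function(t) sum(time == t & event == 1), 0)
  surv <- cumprod(1 - n_event / n_risk)
  gw <- cumsum(n_event / (n_risk * (n_risk - n_event)))
  gw[n_risk == n_event] <- Inf  # S drops to 0: variance term degenerate
  v <- surv^2 * gw
  z <- stats::qnorm(1 - (1 - conf.level) / 2)
  ok <- surv > 0 & surv < 1 & is.finite(gw)
  se_ll <- ifelse(ok, sqrt(gw) / abs(log(surv)), NA_real_)
  lower <- ifelse(ok, surv^exp(z * se_ll), ifelse(surv == 0, 0, NA_real_))
  upper <- ifelse(ok, surv^exp(-z * se_ll), ifelse(surv == 0, 0, NA_real_))
  structure(list(time = ut, n_risk = n_risk, n_event = n_event,
                 surv = surv, var = v, lower = lower, upper = upper,
                 n = length(time), n_events = sum(event),
                 conf.level = conf.level),
            class = "km_curve")
}

#' Evaluate a Kaplan-Meier curve at given times
#'
#' Right-continuous step-function evaluation; `S(t) = 1` before the
#' first event.
#'
#' @param km A `km_curve`.
#' @param t Times at which to evaluate.
#' @return Survival probabilities.
#' @export
km_surv_at <- function(km, t) {
  idx <- findInterval(t, km$time)
  c(1, km$surv)[idx + 1]
}

#' @export
print.km_curve <- function(x, ...) {
  cat("Kaplan-Meier curve: n =", x$n, ", events =", x$n_events, "\n")
  k <- length(x$time)
  show <- unique(round(seq(1, k, length.out = min(k, 6))))
  print(data.frame(time = x$time[show], n_risk = x$n_risk[show],
                   surv = x$surv[show], lower = x$lower[show],
                   upper = x$upper[show]))
  invisible(x)
}

#' Reverse Kaplan-Meier follow-up
#'
#' Median follow-up (with IQR) from the Kaplan-Meier estimator applied
#' with the censoring indicator treated as the event.  A quantile is
#' the first time the curve drops to or below the corresponding level;
#' `NA` with a warning if the curve never reaches it.
#'
#' @param time,event As in [km_estimate()].
#' @return List: `median`, `q1`, `q3` (years), and the underlying
#'   `curve`.
#' @export
reverse_km_followup <- function(time, event) {
  km <- km_estimate(time, 1 - event)
  qat <- function(level) {
    i <- which(km$surv <= level)
    if (!length(i)) return(NA_real_)
    km$time[i[1]]
  }
  med <- qat(0.5)
  if (is.na(med)) {
    warning("reverse-KM curve never reaches 0.5; median follow-up undefined",
            call. = FALSE)
  }
  list(median = med, q1 = qat(0.75), q3 = qat(0.25), curve = km)
}

#' Log-rank (Mantel-Cox) test
#'
#' k-group log-rank test with the hypergeometric variance; the
#' chi-square statistic uses the first k-1 groups and has k-1 degrees
#' of freedom.
#'
#' @param time,event As in [km_estimate()].
#' @param group Group labels (factor or coercible).
#' @return An object of class `logrank_test`: `statistic`, `df`,
#'   `p.value`, `observed`, `expected` per group.
#' @export
logrank <- function(time, event, group) {
  group <- droplevels(as.factor(group))
  k <- nlevels(group)
  if (k < 2) stop("need at least 2 groups", call. = FALSE)
  if (any(table(group) == 0)) stop("empty group", call. = FALSE)
  if (sum(event) < 1) stop("no events", call. = FALSE)
  ut <- sort(unique(time[event == 1]))
  O <- E <- rep(0, k)
  V <- matrix(0, k, k)
  gi <- as.integer(group)
  for (t in ut) {
    at_risk <- time >= t
    n <- sum(at_risk)
    d <- sum(time == t & event == 1)
    ng <- tabulate(gi[at_risk], k)
    dg <- tabulate(gi[time == t & event == 1], k)
    O <- O + dg
    E <- E + d * ng / n
    if (n > 1) {
      p <- ng / n
      V <- V + d * (n - d) / (n - 1) * (diag(p, k) - outer(p, p))
    }
  }
  idx <- seq_len(k - 1)
  u <- (O - E)[idx]
  Vi <- V[idx, idx, drop = FALSE]
  stat <- tryCatch(
    drop(t(u) %*% solve(Vi, u)),
    error = function(e) {
      sv <- svd(Vi)
      pos <- sv$d > max(sv$d) * 1e-10
      drop(t(u) %*% sv$v[, pos, drop = FALSE] %*%
             ((t(sv$u[, pos, drop = FALSE]) %*% u) / sv$d[pos]))
    })
  structure(list(statistic = stat, df = k - 1,
                 p.value = stats::pchisq(stat, k - 1, lower.tail = FALSE),
                 observed = stats::setNames(O, levels(group)),
                 expected = stats::setNames(E, levels(group))),
            class = "logrank_test")
}

#' @export
print.logrank_test <- function(x, ...) {
  cat(sprintf("Log-rank test: chi-square = %.3f on %d df, p = %.4g\n",
              x$statistic, x$df, x$p.value))
  invisible(x)
}

#' Cox proportional hazards fit
#'
#' Partial-likelihood fit with Efron tie handling (Newton-Raphson,
#' log-likelihood tolerance 1e-9, at most 100 iterations) via the
#' survival package; Wald confidence intervals from the observed
#' information.
#'
#' @param data Data frame containing outcome and covariate columns.
#' @param covariates Character vector of covariate column names.  The
#'   preset [cox_preset_multivariable] holds the standard multivariable
#'   adjustment set (age, sex, device, AF, HF etiology, creatinine,
#'   LVEF, ACE-I/ARB, loop diuretics).
#' @param time,event Column names of the outcome (defaults
#'   `time_years`, `event`).
#' @param conf.level Confidence level.
#' @return An object of class `cox_result`: `table` (term, loghr, se,
#'   hr, lower, upper, p), `n`, `n_events`, `loglik`, and the
#'   underlying `fit`.
#' @export
cox_fit <- function(data, covariates, time = "time_years", event = "event",
                    conf.level = 0.95) {
  stopifnot(all(c(time, event, covariates) %in% names(data)))
  for (cv in covariates) {
    v <- data[[cv]]
    if (is.numeric(v) && stats::sd(v, na.rm = TRUE) == 0) {
      stop("constant covariate: ", cv, call. = FALSE)
    }
  }
  n_ev <- sum(data[[event]])
  if (n_ev < length(covariates)) {
    warning("fewer events (", n_ev, ") than covariates (",
            length(covariates), ")", call. = FALSE)
  }
  fml <- stats::as.formula(paste0(
    "survival::Surv(", time, ", ", event, ") ~ ",
    paste(sprintf("`%s`", covariates), collapse = " + ")))
  fit <- survival::coxph(
    fml, data = data, ties = "efron",
    control = survival::coxph.control(eps = 1e-9, iter.max = 100))
  if (anyNA(fit$coefficients)) {
    stop("Cox fit failed (non-identified coefficient); iterations: ",
         fit$iter, call. = FALSE)
  }
  z <- stats::qnorm(1 - (1 - conf.level) / 2)
  beta <- fit$coefficients
  se <- sqrt(diag(fit$var))
  tab <- data.frame(
    term = names(beta), loghr = unname(beta), se = unname(se),
    hr = exp(unname(beta)),
    lower = exp(unname(beta - z * se)), upper = exp(unname(beta + z * se)),
    p = 2 * stats::pnorm(-abs(unname(beta) / unname(se))))
  rownames(tab) <- NULL
  structure(list(table = tab, n = fit$n, n_events = fit$nevent,
                 loglik = fit$loglik[2], fit = fit),
            class = "cox_result")
}

#' @rdname cox_fit
#' @export
cox_preset_multivariable <- c(
  "age", "male", "device_crtd", "af", "ischemic_etiology", "creatinine",
  "lvef", "acei_arb", "loop_diuretic"
)

#' @export
print.cox_result <- function(x, ...) {
  cat("Cox proportional hazards fit: n =", x$n, ", events =", x$n_events,
      "\n")
  tab <- x$table
  tab$hr <- sprintf("%.3f (%.3f-%.3f)", tab$hr, tab$lower, tab$upper)
  print(tab[, c("term", "hr", "p")], row.names = FALSE)
  invisible(x)
}

#' Subgroup forest analysis of the device effect
#'
#' Splits the cohort into the standard clinical subgroups (HF etiology,
#' age < 80 / >= 80, sex, NYHA II vs III-IV, GFR < 60 / >= 60, AF, DM,
#' LVEF < 30 / >= 30) and fits a univariable Cox model of device type
#' within each stratum.  Strata with no events or a constant device
#' column report an undefined (NA) hazard ratio rather than erroring.
#'
#' @param data Cohort data frame with outcome columns and the splitting
#'   covariates.
#' @param device Device indicator column (default `device_crtd`).
#' @param time,event Outcome column names.
#' @return Data frame: `variable`, `stratum`, `n`, `n_events`, `hr`,
#'   `lower`, `upper`, `p`.
#' @export
subgroup_forest <- function(data, device = "device_crtd",
                            time = "time_years", event = "event") {
  defs <- list(
    etiology = list(Ischemic = quote(ischemic_etiology == 1),
                    `Non-ischemic` = quote(ischemic_etiology == 0)),
    age = list(`< 80 years` = quote(age < 80),
               `>= 80 years` = quote(age >= 80)),
    sex = list(Male = quote(male == 1), Female = quote(male == 0)),
    nyha = list(`NYHA II` = quote(nyha_34 == 0),
                `NYHA III-IV` = quote(nyha_34 == 1)),
    gfr = list(`GFR < 60` = quote(gfr < 60), `GFR >= 60` = quote(gfr >= 60)),
    af = list(`History of AF` = quote(af == 1), `No AF` = quote(af == 0)),
    dm = list(`History of DM` = quote(dm == 1), `No DM` = quote(dm == 0)),
    lvef = list(`LVEF < 30%` = quote(lvef < 30),
                `LVEF >= 30%` = quote(lvef >= 30))
  )
  rows <- list()
  for (var in names(defs)) {
    for (lab in names(defs[[var]])) {
      sel <- eval(defs[[var]][[lab]], data)
      sel <- !is.na(sel) & sel
      sub <- data[sel, , drop = FALSE]
      row <- data.frame(variable = var, stratum = lab, n = nrow(sub),
                        n_events = sum(sub[[event]]), hr = NA_real_,
                        lower = NA_real_, upper = NA_real_, p = NA_real_)
      if (nrow(sub) > 1 && sum(sub[[event]]) > 0 &&
          stats::sd(sub[[device]]) > 0) {
        fit <- tryCatch(
          suppressWarnings(cox_fit(sub, device, time = time, event = event)),
          error = function(e) NULL)
        if (!is.null(fit)) {
          row[c("hr", "lower", "upper", "p")] <-
            fit$table[1, c("hr", "lower", "upper", "p")]
        }
      }
      rows[[length(rows) + 1]] <- row
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
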