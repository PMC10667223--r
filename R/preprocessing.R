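# plausibility bounds for continuous features; violations warn, never error
feature_bounds <- list(
  age = c(18, 110), creatinine = c(20, 1500), gfr = c(1, 200),
  lvef = c(5, 80), lvidd = c(20, 100), lvids = c(10, 95)
)

#' Read a cohort table from CSV
#'
#' @param file Path to a CSV with one row per patient, the 16 feature
#'   columns (see [tda_features]) and outcome columns.
#' @return A data frame.
#' @export
read_cohort_csv <- function(file) {
  utils::read.csv(file, stringsAsFactors = FALSE)
}

#' Encode the 16 network features as a numeric matrix
#'
#' Extracts the 16 pre-upgrade features in canonical column order and
#' validates them.  If the cohort stores NYHA class as an I-IV ordinal
#' (`nyha_class` column, roman or numeric) instead of the `nyha_34`
#' indicator, classes III-IV are converted to the indicator.  Binary
#' columns must contain only 0/1/NA; continuous columns outside their
#' plausibility bounds raise warnings.
#'
#' @param cohort Data frame with the feature columns; missing values as
#'   `NA`.
#' @return Numeric matrix (patients x 16) with `NA` for missing entries,
#'   rownames = `patient_id` when present.
#' @export
encode_features <- function(cohort) {
  if (!("nyha_34" %in% names(cohort)) && "nyha_class" %in% names(cohort)) {
    cohort$nyha_34 <- encode_nyha(cohort$nyha_class)
  }
  absent <- setdiff(tda_features, names(cohort))
  if (length(absent)) {
    stop("cohort is missing required feature column(s): ",
         paste(absent, collapse = ", "), call. = FALSE)
  }
  for (f in tda_binary_features) {
    v <- cohort[[f]]
    bad <- !is.na(v) & !(v %in% c(0, 1))
    if (any(bad)) {
      stop("indicator column `", f, "` contains non-binary value(s): ",
           paste(unique(v[bad]), collapse = ", "), call. = FALSE)
    }
  }
  for (f in names(feature_bounds)) {
    v <- cohort[[f]]
    b <- feature_bounds[[f]]
    out <- !is.na(v) & (v < b[1] | v > b[2])
    if (any(out)) {
      warning(sum(out), " value(s) of `", f, "` outside plausibility range [",
              b[1], ", ", b[2], "]", call. = FALSE)
    }
  }
  x <- as.matrix(as.data.frame(lapply(cohort[tda_features], as.numeric)))
  colnames(x) <- tda_features
  if ("patient_id" %in% names(cohort)) {
    if (anyDuplicated(cohort$patient_id)) {
      stop("patient_id values are not unique", call. = FALSE)
    }
    rownames(x) <- cohort$patient_id
  }
  x
}

encode_nyha <- function(v) {
  roman <- c("I" = 1, "II" = 2, "III" = 3, "IV" = 4)
  if (is.character(v) || is.factor(v)) {
    v <- roman[toupper(trimws(as.character(v)))]
  }
  v <- as.numeric(v)
  bad <- !is.na(v) & !(v %in% 1:4)
  if (any(bad)) stop("nyha_class contains values outside I-IV", call. = FALSE)
  as.integer(v >= 3)
}

#' Mean-impute missing entries
#'
#' Replaces every `NA` by its column's observed mean (or by externally
#' supplied means, for applying a frozen transform to new patients).
#' Observed entries are unchanged; the observed column means and the
#' missingness mask are attached as attributes `impute_means` and
#' `missing_mask`.
#'
#' @param x Numeric matrix, possibly with `NA`s.
#' @param means Optional named vector of imputation means; default:
#'   observed column means of `x`.
#' @return The imputed matrix.
#' @export
impute_mean <- function(x, means = NULL) {
  mask <- is.na(x)
  if (is.null(means)) {
    full <- colSums(!mask) == 0
    if (any(full)) {
      stop("cannot mean-impute fully missing column(s): ",
           paste(colnames(x)[full], collapse = ", "), call. = FALSE)
    }
    means <- colMeans(x, na.rm = TRUE)
  }
  for (j in seq_len(ncol(x))) {
    x[mask[, j], j] <- means[[j]]
  }
  attr(x, "impute_means") <- means
  attr(x, "missing_mask") <- mask
  x
}

#' Z-score transform (sample SD)
#'
#' Centers and scales each column by its mean and sample standard
#' deviation (denominator n-1).  Constant columns map to zero with a
#' warning.  The transform parameters are attached as attributes
#' `center` and `scale` so the identical transform can be applied to new
#' patients; attributes of the input (imputation means, missingness
#' mask) are carried over.
#'
#' @param x Numeric matrix with no missing values (impute first).
#' @param center,scale Optional frozen parameters; default: computed
#'   from `x`.
#' @return The transformed matrix.
#' @export
zscore <- function(x, center = NULL, scale = NULL) {
  if (anyNA(x)) stop("zscore requires an imputed (NA-free) matrix",
                     call. = FALSE)
  if (is.null(center)) center <- colMeans(x)
  if (is.null(scale)) {
    scale <- apply(x, 2, stats::sd)
    const <- scale < .Machine$double.eps^0.5
    if (any(const)) {
      warning("constant column(s) mapped to 0: ",
              paste(colnames(x)[const], collapse = ", "), call. = FALSE)
      scale[const] <- Inf  # (x - mean)/Inf = 0
    }
  }
  z <- sweep(sweep(x, 2, center, "-"), 2, scale, "/")
  attr(z, "impute_means") <- attr(x, "impute_means")
  attr(z, "missing_mask") <- attr(x, "missing_mask")
  attr(z, "center") <- center
  attr(z, "scale") <- scale
  z
}

#' Fit the full feature pipeline on a cohort
#'
#' Encodes the 16 features, mean-imputes, then Z-scores — the exact
#' pipeline feeding both the topological network and the classifiers.
#' Transform parameters are learned here and frozen for reuse.
#'
#' @param cohort Cohort data frame.
#' @return Transformed feature matrix with attributes `impute_means`,
#'   `missing_mask`, `center`, `scale`.
#' @export
fit_feature_pipeline <- function(cohort) {
  zscore(impute_mean(encode_features(cohort)))
}

#' Apply a frozen feature transform to new patients
#'
#' Imputes with the training imputation means and applies the training
#' Z-score parameters, as required at prediction time.
#'
#' @param fm A fitted feature matrix from [fit_feature_pipeline()] (or
#'   any matrix carrying `impute_means`, `center`, `scale` attributes).
#' @param new_cohort New cohort data frame (or an already-encoded raw
#'   feature matrix).
#' @return Transformed feature matrix for the new patients.
#' @export
apply_feature_pipeline <- function(fm, new_cohort) {
  x <- if (is.matrix(new_cohort)) new_cohort else encode_features(new_cohort)
  x <- impute_mean(x, means = attr(fm, "impute_means"))
  zscore(x, center = attr(fm, "center"), scale = attr(fm, "scale"))
}
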