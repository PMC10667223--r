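#' Model families for the phenogroup classifiers
#'
#' Each family bundles a hyperparameter grid, a `fit(x, y, params,
#' seed)` function and a `predict_prob(model, x)` function returning a
#' patients x classes probability matrix (columns in the order of
#' `levels(y)`).  Shipped families: multinomial logistic regression,
#' random forest, gradient boosting, RBF support-vector classifier, and
#' a single-hidden-layer perceptron.  The framework is family-agnostic:
#' any list with the same shape can be supplied.
#'
#' @param families Character subset of the shipped families.
#' @return Named list of family definitions.
#' @export
default_model_families <- function(families = c("multinomial",
                                                "random_forest",
                                                "gradient_boosting",
                                                "svm_rbf", "mlp")) {
  all <- list(
    multinomial = list(
      grid = list(list(decay = 0.01)),
      fit = function(x, y, params, seed) {
        set.seed(seed)
        df <- data.frame(.y = y, x, check.names = FALSE)
        nnet::multinom(.y ~ ., df, decay = params$decay, maxit = 300,
                       trace = FALSE)
      },
      predict_prob = function(model, x) {
        p <- stats::predict(model, data.frame(x, check.names = FALSE),
                            type = "probs")
        if (is.null(dim(p))) {
          p <- matrix(p, nrow = 1, dimnames = list(NULL, names(p)))
        }
        p
      }),
    random_forest = list(
      grid = list(list(num_trees = 300, mtry = 4)),
      fit = function(x, y, params, seed) {
        ranger::ranger(x = data.frame(x, check.names = FALSE), y = y,
                       probability = TRUE, num.trees = params$num_trees,
                       mtry = min(params$mtry, ncol(x)), seed = seed,
                       num.threads = 1)
      },
      predict_prob = function(model, x) {
        stats::predict(model, data.frame(x, check.names = FALSE),
                       num.threads = 1)$predictions
      }),
    gradient_boosting = list(
      grid = list(list(nrounds = 150, max_depth = 3, eta = 0.1)),
      fit = function(x, y, params, seed) {
        set.seed(seed)
        dtrain <- xgboost::xgb.DMatrix(as.matrix(x),
                                       label = as.integer(y) - 1)
        model <- xgboost::xgb.train(
          params = list(objective = "multi:softprob",
                        num_class = nlevels(y), max_depth = params$max_depth,
                        eta = params$eta, nthread = 1, seed = seed),
          data = dtrain, nrounds = params$nrounds, verbose = 0)
        list(booster = model, classes = levels(y))
      },
      predict_prob = function(model, x) {
        p <- stats::predict(model$booster,
                            xgboost::xgb.DMatrix(as.matrix(x)))
        if (!is.matrix(p)) {
          p <- matrix(p, ncol = length(model$classes), byrow = TRUE)
        }
        colnames(p) <- model$classes
        p
      }),
    svm_rbf = list(
      grid = list(list(cost = 1)),
      fit = function(x, y, params, seed) {
        set.seed(seed)  # Platt-scaling CV inside svm
        e1071::svm(as.matrix(x), y, kernel = "radial", cost = params$cost,
                   probability = TRUE)
      },
      predict_prob = function(model, x) {
        p <- attr(stats::predict(model, as.matrix(x), probability = TRUE),
                  "probabilities")
        p[, model$levels, drop = FALSE]
      }),
    mlp = list(
      grid = list(list(size = 8, decay = 0.01, maxit = 300),
                  list(size = 16, decay = 0.1, maxit = 300)),
      fit = function(x, y, params, seed) {
        set.seed(seed)
        model <- nnet::nnet(x = as.matrix(x), y = nnet::class.ind(y),
                            size = params$size, decay = params$decay,
                            maxit = params$maxit, softmax = TRUE,
                            trace = FALSE, MaxNWts = 10000)
        list(net = model, classes = levels(y))
      },
      predict_prob = function(model, x) {
        p <- stats::predict(model$net, as.matrix(x))
        colnames(p) <- model$classes
        p
      })
  )
  all[families]
}

#' Nested cross-validation configuration
#'
#' @param outer_folds,inner_folds Fold counts (default 5 and 5): the
#'   inner loop tunes hyperparameters by balanced accuracy, the outer
#'   loop evaluates the tuned models once each.
#' @param families Model families, see [default_model_families()].
#' @param seed Integer seed governing fold assignment and model fits.
#' @param stratified Stratify folds by class (default `TRUE`).
#' @return An object of class `nested_cv_config`.
#' @export
nested_cv_config <- function(outer_folds = 5, inner_folds = 5,
                             families = default_model_families(),
                             seed = 1, stratified = TRUE) {
  if (outer_folds < 2 || inner_folds < 2) {
    stop("fold counts must be >= 2", call. = FALSE)
  }
  if (!length(families) || any(!vapply(families, function(f)
    length(f$grid) > 0, TRUE))) {
    stop("every model family needs a non-empty hyperparameter grid",
         call. = FALSE)
  }
  structure(list(outer_folds = as.integer(outer_folds),
                 inner_folds = as.integer(inner_folds),
                 families = families, seed = as.integer(seed),
                 stratified = isTRUE(stratified)),
            class = "nested_cv_config")
}

# stratified fold assignment: within each class, shuffled round-robin
stratified_folds <- function(y, k, seed) {
  set.seed(seed)
  fold <- integer(length(y))
  for (cl in levels(y)) {
    idx <- sample(which(y == cl))
    fold[idx] <- rep_len(seq_len(k), length(idx))
  }
  fold
}

# label from a probability matrix; ties go to the higher-risk class
# (classes are ordered low < intermediate < high)
prob_to_label <- function(prob, classes) {
  lab <- apply(prob, 1, function(p) max(which(p >= max(p) - 1e-12)))
  factor(classes[lab], levels = classes)
}

#' Train the nested cross-validated classifier ensemble
#'
#' Stratified, disjoint outer folds; within each outer-training split a
#' grid search over all family/hyperparameter candidates is scored by
#' inner-CV balanced accuracy, the winner refit on the full
#' outer-training split and evaluated once on the outer-test split.
#' All preprocessing (mean imputation, Z-scoring) is fit on the
#' training side of every split only — no information leaks into
#' evaluation.  The 5 tuned outer-fold models form the ensemble applied
#' to new patients.
#'
#' @param x_raw Raw (unimputed, unscaled) feature matrix from
#'   [encode_features()].
#' @param labels Factor of phenogroup labels (levels low <
#'   intermediate < high).
#' @param cfg A [nested_cv_config()].
#' @return An object of class `phenogroup_ensemble`: `members` (one per
#'   outer fold: family, params, model, frozen preprocessing
#'   parameters, inner scores), `classes`, `outer_fold` assignment,
#'   `metrics` (per-fold and aggregate report), `cfg`.
#' @export
nested_cv_train <- function(x_raw, labels, cfg = nested_cv_config()) {
  labels <- droplevels(as.factor(labels))
  stopifnot(nrow(x_raw) == length(labels))
  if (nlevels(labels) < 3) {
    stop("need at least 3 classes present", call. = FALSE)
  }
  if (any(table(labels) < cfg$outer_folds)) {
    stop("stratification error: every class needs at least ",
         cfg$outer_folds, " members", call. = FALSE)
  }
  classes <- levels(labels)
  candidates <- list()
  for (fam in names(cfg$families)) {
    for (params in cfg$families[[fam]]$grid) {
      candidates[[length(candidates) + 1]] <-
        list(family = fam, params = params)
    }
  }

  outer <- if (cfg$stratified) {
    stratified_folds(labels, cfg$outer_folds, cfg$seed)
  } else {
    set.seed(cfg$seed)
    sample(rep_len(seq_len(cfg$outer_folds), length(labels)))
  }

  fit_one <- function(cand, x_tr_raw, y_tr, x_ev_raw, seed) {
    fm <- zscore(impute_mean(x_tr_raw))
    x_tr <- unclass_matrix(fm)
    x_ev <- unclass_matrix(apply_feature_pipeline(fm, x_ev_raw))
    fam <- cfg$families[[cand$family]]
    model <- fam$fit(x_tr, y_tr, cand$params, seed)
    prob <- fam$predict_prob(model, x_ev)
    prob <- prob[, classes, drop = FALSE]
    list(model = model, prob = prob, preprocess = list(
      impute_means = attr(fm, "impute_means"), center = attr(fm, "center"),
      scale = attr(fm, "scale")))
  }

  members <- list()
  fold_metrics <- list()
  for (f in seq_len(cfg$outer_folds)) {
    tr <- which(outer != f)
    te <- which(outer == f)
    y_tr <- labels[tr]
    inner <- stratified_folds(y_tr, cfg$inner_folds, cfg$seed + 1000L * f)
    scores <- vapply(seq_along(candidates), function(ci) {
      accs <- vapply(seq_len(cfg$inner_folds), function(g) {
        itr <- which(inner != g)
        iva <- which(inner == g)
        res <- fit_one(candidates[[ci]],
                       x_raw[tr[itr], , drop = FALSE], y_tr[itr],
                       x_raw[tr[iva], , drop = FALSE],
                       seed = cfg$seed + 7L * f + 13L * g + 101L * ci)
        pred <- prob_to_label(res$prob, classes)
        balanced_accuracy(y_tr[iva], pred)
      }, 0)
      mean(accs)
    }, 0)
    best <- which.max(scores)  # tie -> first candidate
    res <- fit_one(candidates[[best]], x_raw[tr, , drop = FALSE], y_tr,
                   x_raw[te, , drop = FALSE], seed = cfg$seed + 7L * f)
    pred <- prob_to_label(res$prob, classes)
    fold_metrics[[f]] <- compute_metrics(labels[te], pred, res$prob)
    members[[f]] <- list(
      family = candidates[[best]]$family, params = candidates[[best]]$params,
      model = res$model, preprocess = res$preprocess,
      inner_scores = stats::setNames(
        scores, vapply(candidates, `[[`, "", "family")),
      outer_fold = f)
  }

  structure(list(members = members, classes = classes, outer_fold = outer,
                 metrics = aggregate_metrics(fold_metrics), cfg = cfg),
            class = "phenogroup_ensemble")
}

unclass_matrix <- function(x) {
  attributes(x)[setdiff(names(attributes(x)), c("dim", "dimnames"))] <- NULL
  x
}

#' Predict phenogroups for new patients with the ensemble
#'
#' Each member applies its own frozen preprocessing, the per-class
#' probabilities are averaged over the members, and the label is the
#' argmax (probability ties resolved towards the higher-risk class).
#'
#' @param ensemble A `phenogroup_ensemble`.
#' @param x_raw Raw feature matrix (same 16 columns as in training) or
#'   a cohort data frame.
#' @return List: `prob` (patients x classes, rows sum to 1), `class`
#'   (factor).
#' @export
predict_ensemble <- function(ensemble, x_raw) {
  if (is.data.frame(x_raw)) x_raw <- encode_features(x_raw)
  if (!identical(colnames(x_raw), tda_features)) {
    stop("feature matrix must have the 16 canonical columns in order",
         call. = FALSE)
  }
  classes <- ensemble$classes
  prob <- 0
  for (m in ensemble$members) {
    x <- impute_mean(x_raw, means = m$preprocess$impute_means)
    x <- zscore(x, center = m$preprocess$center, scale = m$preprocess$scale)
    x <- unclass_matrix(x)
    fam <- ensemble$cfg$families[[m$family]]
    p <- fam$predict_prob(m$model, x)[, classes, drop = FALSE]
    prob <- prob + p
  }
  prob <- prob / length(ensemble$members)
  prob <- prob / rowSums(prob)
  list(prob = prob, class = prob_to_label(prob, classes))
}

#' Balanced accuracy
#'
#' Unweighted mean of the per-class recalls; classes with zero support
#' are excluded with a warning.
#'
#' @param y_true,y_pred Factors (or coercible) of true and predicted
#'   labels.
#' @return Scalar in `[0, 1]`.
#' @export
balanced_accuracy <- function(y_true, y_pred) {
  y_true <- as.factor(y_true)
  y_pred <- factor(y_pred, levels = levels(y_true))
  rec <- per_class_recall(y_true, y_pred)
  if (anyNA(rec)) {
    warning("class(es) with zero support excluded from balanced accuracy: ",
            paste(names(rec)[is.na(rec)], collapse = ", "), call. = FALSE)
  }
  mean(rec, na.rm = TRUE)
}

per_class_recall <- function(y_true, y_pred) {
  vapply(levels(y_true), function(cl) {
    n <- sum(y_true == cl)
    if (n == 0) NA_real_ else sum(y_true == cl & y_pred == cl) / n
  }, 0)
}

# rank-based (Mann-Whitney) AUC with midrank tie handling
auc_rank <- function(truth, score) {
  npos <- sum(truth)
  nneg <- sum(!truth)
  if (npos == 0 || nneg == 0) return(NA_real_)
  r <- rank(score)
  (sum(r[truth]) - npos * (npos + 1) / 2) / (npos * nneg)
}

#' Multi-class performance metrics
#'
#' Balanced accuracy, accuracy, micro- and macro-averaged precision,
#' recall and F1, and micro/macro one-vs-rest AUC.  Micro metrics pool
#' the one-vs-rest decisions across classes; macro metrics average the
#' per-class values (classes with zero support excluded with a
#' warning).
#'
#' @param y_true,y_pred Label factors.
#' @param prob Optional patients x classes probability matrix (rows sum
#'   to 1) for the AUCs.
#' @return List of metrics plus the `confusion` matrix and a
#'   `per_class` data frame.
#' @export
compute_metrics <- function(y_true, y_pred, prob = NULL) {
  y_true <- as.factor(y_true)
  classes <- levels(y_true)
  y_pred <- factor(y_pred, levels = classes)
  conf <- table(true = y_true, predicted = y_pred)
  support <- rowSums(conf)
  if (any(support == 0)) {
    warning("class(es) with zero support excluded from macro averages: ",
            paste(classes[support == 0], collapse = ", "), call. = FALSE)
  }
  tp <- diag(conf)
  fp <- colSums(conf) - tp
  fn <- rowSums(conf) - tp
  recall <- ifelse(support == 0, NA, tp / (tp + fn))
  precision <- ifelse(tp + fp == 0, NA, tp / (tp + fp))
  f1 <- ifelse(is.na(precision) | is.na(recall) | precision + recall == 0,
               NA, 2 * precision * recall / (precision + recall))
  n <- length(y_true)
  # micro: pool one-vs-rest decisions (for single-label data micro
  # precision = recall = accuracy)
  micro_tp <- sum(tp)
  micro_fp <- sum(fp)
  micro_fn <- sum(fn)
  micro_p <- micro_tp / (micro_tp + micro_fp)
  micro_r <- micro_tp / (micro_tp + micro_fn)
  out <- list(
    confusion = conf,
    per_class = data.frame(class = classes, support = as.integer(support),
                           precision = unname(precision),
                           recall = unname(recall), f1 = unname(f1)),
    balanced_accuracy = mean(recall, na.rm = TRUE),
    accuracy = sum(tp) / n,
    precision_macro = mean(precision, na.rm = TRUE),
    precision_micro = micro_p,
    recall_macro = mean(recall, na.rm = TRUE),
    recall_micro = micro_r,
    f1_macro = mean(f1, na.rm = TRUE),
    f1_micro = 2 * micro_p * micro_r / (micro_p + micro_r))
  if (!is.null(prob)) {
    prob <- prob[, classes, drop = FALSE]
    per_auc <- vapply(classes, function(cl) {
      auc_rank(y_true == cl, prob[, cl])
    }, 0)
    out$auc_macro <- mean(per_auc, na.rm = TRUE)
    ind <- outer(as.character(y_true), classes, "==")
    out$auc_micro <- auc_rank(as.vector(ind), as.vector(prob))
    out$per_class$auc <- unname(per_auc)
  }
  out
}

scalar_metric_names <- c("balanced_accuracy", "accuracy", "precision_macro",
                         "precision_micro", "recall_macro", "recall_micro",
                         "f1_macro", "f1_micro", "auc_macro", "auc_micro")

#' Aggregate per-fold metric reports
#'
#' Mean across folds with a normal-approximation 95% CI
#' (mean +/- 1.96 * SD / sqrt(folds)) — reported as a methodological
#' assumption, not an exact interval.
#'
#' @param fold_metrics List of [compute_metrics()] results.
#' @return List: `per_fold` data frame, `aggregate` data frame (metric,
#'   mean, sd, lower, upper), `confusion` (summed).
#' @export
aggregate_metrics <- function(fold_metrics) {
  present <- scalar_metric_names[scalar_metric_names %in%
                                   names(fold_metrics[[1]])]
  per_fold <- do.call(rbind, lapply(seq_along(fold_metrics), function(i) {
    vals <- fold_metrics[[i]][present]
    cbind(data.frame(fold = i), as.data.frame(vals))
  }))
  k <- length(fold_metrics)
  agg <- do.call(rbind, lapply(present, function(mn) {
    v <- per_fold[[mn]]
    data.frame(metric = mn, mean = mean(v), sd = stats::sd(v),
               lower = mean(v) - 1.96 * stats::sd(v) / sqrt(k),
               upper = mean(v) + 1.96 * stats::sd(v) / sqrt(k))
  }))
  conf <- Reduce(`+`, lapply(fold_metrics, `[[`, "confusion"))
  list(per_fold = per_fold, aggregate = agg, confusion = conf)
}

#' @export
print.phenogroup_ensemble <- function(x, ...) {
  cat("Phenogroup classifier ensemble:", length(x$members), "members\n")
  fams <- vapply(x$members, `[[`, "", "family")
  cat("  selected families:", paste(fams, collapse = ", "), "\n")
  agg <- x$metrics$aggregate
  ba <- agg[agg$metric == "balanced_accuracy", ]
  cat(sprintf("  balanced accuracy: %.3f (%.3f-%.3f)\n",
              ba$mean, ba$lower, ba$upper))
  invisible(x)
}
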