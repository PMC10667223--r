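#' Pipeline configuration
#'
#' Collects every tunable of the phenomapping pipeline: the cover
#' (resolution 25, gain 2.1, equalized — the published network
#' settings), the in-cell clustering histogram bins, the Louvain
#' autogrouping target (14) and seed, the merge balance cap, and the
#' Kaplan-Meier reporting horizons.
#'
#' @param resolution,gain,equalized Cover parameters, see
#'   [cover_config()].
#' @param cluster_bins Histogram bins for [cluster_cell()].
#' @param target_groups Louvain autogroup target count.
#' @param louvain_seed Seed for the Louvain heuristic.
#' @param balance_cap Merge size cap, see [merge_to_three()].
#' @param horizons Years at which KM mortality is reported.
#' @return An object of class `phenomap_config`.
#' @export
phenomap_config <- function(resolution = 25, gain = 2.1, equalized = TRUE,
                            cluster_bins = 10, target_groups = 14,
                            louvain_seed = 1, balance_cap = 1.4,
                            horizons = c(5, 10)) {
  structure(list(
    cover = cover_config(resolution, gain, equalized),
    cluster_bins = cluster_bins, target_groups = target_groups,
    louvain_seed = louvain_seed, balance_cap = balance_cap,
    horizons = horizons), class = "phenomap_config")
}

#' Read a pipeline configuration from YAML or JSON
#'
#' Keys mirror the arguments of [phenomap_config()]; absent keys keep
#' their defaults.
#'
#' @param path Path to a `.yaml`/`.yml` or `.json` file.
#' @return A `phenomap_config`.
#' @export
read_phenomap_config <- function(path) {
  vals <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  known <- names(formals(phenomap_config))
  unknown <- setdiff(names(vals), known)
  if (length(unknown)) {
    stop("unknown config key(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  do.call(phenomap_config, vals)
}

#' Run the phenomapping pipeline on a cohort
#'
#' Executes preprocess -> topological network -> phenogrouping on a
#' cohort table, returning everything downstream analyses (survival,
#' classifier training) consume.  Fully deterministic given the
#' configuration seeds.
#'
#' @param cohort Cohort data frame: the 16 features plus `time_years`
#'   and `event` (see [encode_features()], [apply_censoring()]).
#' @param config A [phenomap_config()].
#' @return An object of class `phenomap_run`: `features` (fitted
#'   feature matrix), `graph` (`mapper_graph`, colored by outcome),
#'   `partition` (`phenogroup_partition` with patient assignment),
#'   `assignment` (data frame over all cohort rows: `patient_id`,
#'   `phenogroup`, `n_candidate_groups`, `outlier`), `config`.
#' @export
run_phenomap <- function(cohort, config = phenomap_config()) {
  stopifnot(all(c("time_years", "event") %in% names(cohort)))
  if (anyNA(cohort$time_years) || anyNA(cohort$event)) {
    stop("outcome fields must not be missing", call. = FALSE)
  }
  features <- fit_feature_pipeline(cohort)
  graph <- mapper_network(features, cover = config$cover,
                          bins = config$cluster_bins, event = cohort$event)
  partition <- phenogroup(graph, cohort$event,
                          target_groups = config$target_groups,
                          seed = config$louvain_seed,
                          balance_cap = config$balance_cap)
  assignment <- data.frame(
    patient = seq_len(nrow(cohort)),
    patient_id = if ("patient_id" %in% names(cohort)) {
      cohort$patient_id
    } else {
      as.character(seq_len(nrow(cohort)))
    },
    phenogroup = factor(NA, levels = group_levels),
    n_candidate_groups = 0L,
    outlier = FALSE)
  p2g <- partition$patient_to_group
  assignment$phenogroup[p2g$patient] <- p2g$phenogroup
  assignment$n_candidate_groups[p2g$patient] <- p2g$n_candidate_groups
  assignment$outlier[graph$outliers] <- TRUE
  structure(list(features = features, graph = graph, partition = partition,
                 assignment = assignment, config = config),
            class = "phenomap_run")
}

#' @export
print.phenomap_run <- function(x, ...) {
  cat("Phenomapping run\n")
  print(x$graph)
  print(x$partition)
  invisible(x)
}

#' Survival summary of a phenomapping run
#'
#' Kaplan-Meier mortality at the reporting horizons, the k-group
#' log-rank test, phenogroup hazard ratios vs the low-risk group, the
#' device hazard ratio within each phenogroup, and the reverse-KM
#' follow-up.
#'
#' @param run A `phenomap_run`.
#' @param cohort The cohort the run was built from.
#' @return List: `km_by_group`, `mortality_at_horizons`, `logrank`,
#'   `cox_phenogroup` (HRs vs low), `cox_device_by_group`,
#'   `followup` (reverse-KM).
#' @export
phenomap_survival <- function(run, cohort) {
  asg <- run$assignment
  keep <- !is.na(asg$phenogroup)
  dat <- cohort[keep, , drop = FALSE]
  dat$phenogroup <- asg$phenogroup[keep]
  km_by_group <- lapply(split(dat, dat$phenogroup), function(d) {
    km_estimate(d$time_years, d$event)
  })
  horizons <- run$config$horizons
  mort <- do.call(rbind, lapply(names(km_by_group), function(g) {
    data.frame(phenogroup = g, horizon = horizons,
               mortality = 1 - km_surv_at(km_by_group[[g]], horizons))
  }))
  lr <- logrank(dat$time_years, dat$event, dat$phenogroup)
  dat$phenogroup_intermediate <- as.integer(dat$phenogroup == "intermediate")
  dat$phenogroup_high <- as.integer(dat$phenogroup == "high")
  cox_pg <- cox_fit(dat, c("phenogroup_intermediate", "phenogroup_high"))
  cox_dev <- lapply(split(dat, dat$phenogroup), function(d) {
    tryCatch(suppressWarnings(cox_fit(d, "device_crtd")),
             error = function(e) NULL)
  })
  list(km_by_group = km_by_group, mortality_at_horizons = mort,
       logrank = lr, cox_phenogroup = cox_pg,
       cox_device_by_group = cox_dev,
       followup = reverse_km_followup(dat$time_years, dat$event))
}

#' Write the artifacts of a phenomapping run to a directory
#'
#' Emits the network (GraphML + JSON), the phenogroup assignment CSV,
#' the merge trace JSON and the survival tables JSON.
#'
#' @param run A `phenomap_run`.
#' @param cohort The cohort the run was built from.
#' @param dir Output directory (created if absent).
#' @return The directory, invisibly.
#' @export
write_phenomap_run <- function(run, cohort, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  export_mapper_graphml(run$graph, file.path(dir, "graph.graphml"))
  export_mapper_json(run$graph, file.path(dir, "graph.json"))
  utils::write.csv(run$assignment, file.path(dir, "phenogroups.csv"),
                   row.names = FALSE)
  jsonlite::write_json(run$partition$merge_trace,
                       file.path(dir, "merge_trace.json"), digits = NA)
  surv <- phenomap_survival(run, cohort)
  jsonlite::write_json(
    list(
      mortality_at_horizons = surv$mortality_at_horizons,
      logrank = list(statistic = surv$logrank$statistic,
                     df = surv$logrank$df, p = surv$logrank$p.value),
      cox_phenogroup = surv$cox_phenogroup$table,
      cox_device_by_group = lapply(surv$cox_device_by_group, function(f) {
        if (is.null(f)) NULL else f$table
      }),
      followup_median = surv$followup$median,
      followup_iqr = c(surv$followup$q1, surv$followup$q3)),
    file.path(dir, "survival.json"), auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
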