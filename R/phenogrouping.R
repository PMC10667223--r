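#' Louvain autogrouping of the Mapper graph
#'
#' Modularity optimization on the node graph with edge weight = number
#' of shared patients.  When `target_groups` is given, the Louvain
#' resolution parameter is tuned by bisection until the community count
#' is within `tol_groups` of the target (the closest resolution found is
#' used if the window cannot be hit exactly).  Deterministic given
#' `seed`.
#'
#' @param graph A connected `mapper_graph` (after outlier removal).
#' @param resolution Louvain resolution parameter (ignored when
#'   `target_groups` is set).
#' @param seed Integer seed for the Louvain heuristic.
#' @param target_groups Desired community count (e.g. 14), or `NULL`.
#' @param tol_groups Acceptable deviation from `target_groups`.
#' @return List: `membership` (integer per node), `n_groups`,
#'   `resolution`, `modularity`.
#' @export
louvain_autogroup <- function(graph, resolution = 1, seed = 1,
                              target_groups = NULL, tol_groups = 2) {
  n <- length(graph$members)
  if (n < 2) {
    warning("graph has fewer than 2 nodes; returning a single group",
            call. = FALSE)
    return(list(membership = rep(1L, n), n_groups = 1L,
                resolution = resolution, modularity = NA_real_))
  }
  g <- as_igraph_mapper(graph)
  run <- function(r) {
    set.seed(seed)
    igraph::cluster_louvain(g, weights = igraph::E(g)$weight, resolution = r)
  }
  if (is.null(target_groups)) {
    cl <- run(resolution)
  } else {
    # community count grows with resolution; bracket then bisect
    lo <- 0.05
    hi <- 1
    cl_hi <- run(hi)
    it <- 0
    while (length(cl_hi) < target_groups && it < 20) {
      hi <- hi * 2
      cl_hi <- run(hi)
      it <- it + 1
    }
    cl_lo <- run(lo)
    best <- cl_hi
    best_r <- hi
    for (cand in list(list(cl_lo, lo), list(cl_hi, hi))) {
      if (abs(length(cand[[1]]) - target_groups) <
          abs(length(best) - target_groups)) {
        best <- cand[[1]]; best_r <- cand[[2]]
      }
    }
    for (it in seq_len(40)) {
      if (abs(length(best) - target_groups) <= tol_groups) break
      mid <- (lo + hi) / 2
      cl_mid <- run(mid)
      if (abs(length(cl_mid) - target_groups) <
          abs(length(best) - target_groups)) {
        best <- cl_mid; best_r <- mid
      }
      if (length(cl_mid) < target_groups) lo <- mid else hi <- mid
    }
    cl <- best
    resolution <- best_r
  }
  memb <- as.integer(igraph::membership(cl))
  list(membership = memb, n_groups = length(unique(memb)),
       resolution = resolution,
       modularity = igraph::modularity(g, memb,
                                       weights = igraph::E(g)$weight))
}

# unique member patients of each group of a node partition
group_patient_sets <- function(membership, graph) {
  lapply(split(seq_along(membership), membership), function(nodes) {
    unique(unlist(graph$members[nodes]))
  })
}

#' Per-group mortality
#'
#' Crude death proportion among the unique member patients of each
#' group (a patient present in several nodes of one group counts once).
#'
#' @param membership Integer group id per node.
#' @param graph A `mapper_graph`.
#' @param event 0/1 outcome vector indexed by patient.
#' @return Data frame: `group`, `n_patients`, `n_events`, `mortality`.
#' @export
group_mortality <- function(membership, graph, event) {
  sets <- group_patient_sets(membership, graph)
  if (any(lengths(sets) == 0)) stop("empty group", call. = FALSE)
  rows <- lapply(names(sets), function(gid) {
    ev <- event[sets[[gid]]]
    if (anyNA(ev)) stop("group ", gid, " has member(s) without an outcome",
                        call. = FALSE)
    data.frame(group = as.integer(gid), n_patients = length(ev),
               n_events = sum(ev), mortality = mean(ev))
  })
  do.call(rbind, rows)
}

#' Merge autogroups into three phenogroups
#'
#' Greedy survival-guided merging: at each step the pair of adjacent
#' groups (joined by at least one Mapper edge) with the smallest
#' absolute mortality difference is merged, skipping merges that would
#' push a group above `balance_cap * (retained patients / 3)` ("nearly
#' equal" group sizes); if no merge is permissible the cap is relaxed by
#' a factor 1.1 and the step retried.  Ties in mortality difference go
#' to the pair with the smaller combined patient count, then the lower
#' group ids.  Stops at exactly 3 groups, which are relabeled
#' low/intermediate/high by mortality.
#'
#' @param membership Initial node partition (integer per node), e.g.
#'   from [louvain_autogroup()].
#' @param graph A connected `mapper_graph`.
#' @param event 0/1 outcome vector indexed by patient.
#' @param balance_cap Size cap multiplier (default 1.4).
#' @return An object of class `phenogroup_partition`: `node_to_group`
#'   (factor low/intermediate/high per node), `group_summary`,
#'   `merge_trace` (data frame, one row per merge), `initial_groups`.
#' @export
merge_to_three <- function(membership, graph, event, balance_cap = 1.4) {
  memb <- as.integer(membership)
  initial_groups <- length(unique(memb))
  if (initial_groups < 3) {
    stop("need at least 3 initial groups (got ", initial_groups, ")",
         call. = FALSE)
  }
  total <- length(unique(unlist(graph$members)))
  cap <- balance_cap
  trace <- list()
  step <- 0

  group_stats <- function(memb) {
    gm <- group_mortality(memb, graph, event)
    gm[order(gm$group), , drop = FALSE]
  }
  adjacency_pairs <- function(memb) {
    if (!nrow(graph$edges)) return(matrix(integer(0), 0, 2))
    ga <- memb[graph$edges[, 1]]
    gb <- memb[graph$edges[, 2]]
    keep <- ga != gb
    p <- cbind(pmin(ga, gb), pmax(ga, gb))[keep, , drop = FALSE]
    unique(p)
  }

  while (length(unique(memb)) > 3) {
    gm <- group_stats(memb)
    adj <- adjacency_pairs(memb)
    if (!nrow(adj)) {
      stop("group adjacency is disconnected; cannot reduce to 3 groups ",
           "(trace: ", nrow(do.call(rbind, trace)), " merges done)",
           call. = FALSE)
    }
    mort <- stats::setNames(gm$mortality, gm$group)
    size <- stats::setNames(gm$n_patients, gm$group)
    sets <- group_patient_sets(memb, graph)
    merged_size <- apply(adj, 1, function(p) {
      length(unique(c(sets[[as.character(p[1])]],
                      sets[[as.character(p[2])]])))
    })
    diff <- abs(mort[as.character(adj[, 1])] - mort[as.character(adj[, 2])])
    allowed <- merged_size <= cap * total / 3
    if (!any(allowed)) {
      cap <- cap * 1.1
      next
    }
    comb <- size[as.character(adj[, 1])] + size[as.character(adj[, 2])]
    ord <- order(!allowed, diff, comb, adj[, 1], adj[, 2])[1]
    a <- adj[ord, 1]
    b <- adj[ord, 2]
    step <- step + 1
    trace[[step]] <- data.frame(
      step = step, group_a = a, group_b = b,
      mortality_diff = unname(diff[ord]),
      merged_size = unname(merged_size[ord]),
      n_groups_after = length(unique(memb)) - 1L,
      balance_cap = cap)
    memb[memb == b] <- a
  }

  gm <- group_stats(memb)
  ord <- order(gm$mortality, gm$group)
  labels <- stats::setNames(group_levels, gm$group[ord])
  node_to_group <- factor(labels[as.character(memb)], levels = group_levels)
  gm$phenogroup <- factor(labels[as.character(gm$group)],
                          levels = group_levels)
  gm <- gm[order(gm$phenogroup), c("phenogroup", "n_patients", "n_events",
                                   "mortality")]
  rownames(gm) <- NULL
  structure(
    list(node_to_group = node_to_group, group_summary = gm,
         merge_trace = if (step) do.call(rbind, trace) else
           data.frame(step = integer(0), group_a = integer(0),
                      group_b = integer(0), mortality_diff = numeric(0),
                      merged_size = integer(0), n_groups_after = integer(0),
                      balance_cap = numeric(0)),
         initial_groups = initial_groups, balance_cap = balance_cap),
    class = "phenogroup_partition")
}

#' Assign each patient a unique phenogroup label
#'
#' A patient's candidate groups are the phenogroups of the nodes
#' containing them; the unique label is the majority group by node
#' count, ties going to the higher-mortality group (clinically
#' conservative).  Patients whose nodes span more than one phenogroup
#' are recorded as multi-membership.
#'
#' @param partition A `phenogroup_partition`.
#' @param graph The `mapper_graph` the partition was built on.
#' @return List: `patient_to_group` (data frame: `patient`, `phenogroup`,
#'   `n_candidate_groups`), `multi_membership` (data frame: `patient`,
#'   `groups`).
#' @export
assign_patients <- function(partition, graph) {
  pt <- unlist(graph$members, use.names = FALSE)
  grp <- rep(partition$node_to_group, lengths(graph$members))
  by_pt <- split(as.integer(grp), pt)
  assign_one <- function(g_idx) {
    counts <- tabulate(g_idx, 3)
    cand <- which(counts == max(counts))
    max(cand)  # tie -> higher-risk (levels ordered low < intermediate < high)
  }
  patients <- as.integer(names(by_pt))
  lab <- vapply(by_pt, assign_one, 0)
  n_cand <- vapply(by_pt, function(g) length(unique(g)), 0)
  p2g <- data.frame(
    patient = patients,
    phenogroup = factor(group_levels[lab], levels = group_levels),
    n_candidate_groups = as.integer(n_cand))
  p2g <- p2g[order(p2g$patient), ]
  rownames(p2g) <- NULL
  multi <- p2g[p2g$n_candidate_groups > 1, "patient", drop = FALSE]
  multi$groups <- vapply(
    as.character(multi$patient),
    function(p) paste(group_levels[sort(unique(by_pt[[p]]))], collapse = "+"),
    "")
  rownames(multi) <- NULL
  list(patient_to_group = p2g, multi_membership = multi)
}

#' Phenogroup a Mapper network end to end
#'
#' Louvain autogrouping (tuned towards `target_groups` communities),
#' survival-guided merging to three phenogroups, and unique patient
#' assignment.
#'
#' @inheritParams louvain_autogroup
#' @inheritParams merge_to_three
#' @return A `phenogroup_partition` with `autogroups` (the Louvain
#'   result), `patient_to_group` and `multi_membership` attached.
#' @export
phenogroup <- function(graph, event, target_groups = 14, seed = 1,
                       balance_cap = 1.4) {
  auto <- louvain_autogroup(graph, seed = seed, target_groups = target_groups)
  part <- merge_to_three(auto$membership, graph, event, balance_cap)
  asg <- assign_patients(part, graph)
  part$autogroups <- auto
  part$patient_to_group <- asg$patient_to_group
  part$multi_membership <- asg$multi_membership
  part
}

#' @export
print.phenogroup_partition <- function(x, ...) {
  cat("Phenogroup partition (", x$initial_groups, " autogroups -> 3):\n",
      sep = "")
  print(x$group_summary)
  if (!is.null(x$multi_membership)) {
    cat(nrow(x$multi_membership), "patient(s) with multi-group membership\n")
  }
  invisible(x)
}

#' Write phenogroup assignments to CSV
#'
#' @param partition A `phenogroup_partition` from [phenogroup()].
#' @param file Output path.
#' @param patient_id Optional character ids to translate patient row
#'   indices.
#' @export
write_phenogroups_csv <- function(partition, file, patient_id = NULL) {
  df <- partition$patient_to_group
  if (!is.null(patient_id)) df$patient_id <- patient_id[df$patient]
  utils::write.csv(df, file, row.names = FALSE)
  invisible(file)
}
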