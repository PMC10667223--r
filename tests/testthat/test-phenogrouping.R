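# hand-built mapper_graph: one private patient per node plus one shared
# patient per requested edge (so every edge has weight 1)
toy_graph <- function(n_nodes, edges, extra_members = NULL) {
  members <- lapply(seq_len(n_nodes), function(i) i)
  nxt <- n_nodes + 1L
  if (length(edges)) {
    for (k in seq_len(nrow(edges))) {
      members[[edges[k, 1]]] <- c(members[[edges[k, 1]]], nxt)
      members[[edges[k, 2]]] <- c(members[[edges[k, 2]]], nxt)
      nxt <- nxt + 1L
    }
  }
  if (!is.null(extra_members)) {
    for (i in seq_along(extra_members)) {
      members[[i]] <- c(members[[i]], extra_members[[i]])
    }
  }
  structure(list(
    members = members,
    node_info = data.frame(id = seq_len(n_nodes), cell_x = seq_len(n_nodes),
                           cell_y = 1, size = lengths(members)),
    edges = if (length(edges)) {
      e <- cbind(from = pmin(edges[, 1], edges[, 2]),
                 to = pmax(edges[, 1], edges[, 2]))
      e[order(e[, 1], e[, 2]), , drop = FALSE]
    } else {
      matrix(integer(0), 0, 2)
    },
    n_points = max(unlist(members)), outliers = integer(0)),
    class = "mapper_graph")
}

# all set partitions of 1..n (restricted growth strings)
set_partitions <- function(n) {
  out <- list()
  recurse <- function(assign, k) {
    i <- length(assign) + 1
    if (i > n) {
      out[[length(out) + 1]] <<- assign
      return()
    }
    for (g in seq_len(k + 1)) recurse(c(assign, g), max(k, g))
  }
  recurse(integer(0), 0)
  out
}

test_that("Louvain finds the modularity-optimal split of two cliques", {
  clique <- function(v) t(combn(v, 2))
  edges <- rbind(clique(1:4), clique(5:8), c(4, 5))
  g <- toy_graph(8, edges)
  ig <- as_igraph_mapper(g)
  # brute force over all 4140 set partitions of the 8 nodes
  parts <- set_partitions(8)
  mods <- vapply(parts, function(p) {
    igraph::modularity(ig, p, weights = igraph::E(ig)$weight)
  }, 0)
  best <- parts[[which.max(mods)]]
  expect_equal(best, c(1, 1, 1, 1, 2, 2, 2, 2))
  auto <- louvain_autogroup(g, seed = 1)
  expect_equal(auto$n_groups, 2)
  expect_equal(unname(tapply(seq_len(8), auto$membership, paste,
                             collapse = ",")),
               c("1,2,3,4", "5,6,7,8"), ignore_attr = TRUE)
  expect_equal(auto$modularity, max(mods), tolerance = 1e-12)
  # returned partition is at least as modular as the trivial one
  expect_gte(auto$modularity,
             igraph::modularity(ig, rep(1, 8),
                                weights = igraph::E(ig)$weight))
})

test_that("a single-node graph yields one group with a warning", {
  g <- toy_graph(1, matrix(integer(0), 0, 2))
  expect_warning(auto <- louvain_autogroup(g), "single group")
  expect_equal(auto$membership, 1L)
})

test_that("resolution tuning approaches the requested autogroup count", {
  run <- default_run_1000()
  auto <- run$partition$autogroups
  expect_lte(abs(auto$n_groups - 14), 2)
})

test_that("group mortality counts unique patients once", {
  g <- toy_graph(2, matrix(integer(0), 0, 2),
                 extra_members = list(c(10L, 11L), c(11L, 12L)))
  # one group containing both nodes: patients {1,10,11} U {2,11,12}
  ev <- rep(0, 12)
  ev[c(1, 11)] <- 1
  gm <- group_mortality(c(1, 1), g, ev)
  expect_equal(gm$n_patients, 5)  # 11 counted once
  expect_equal(gm$mortality, 2 / 5)
  # simple rate
  g2 <- toy_graph(1, matrix(integer(0), 0, 2),
                  extra_members = list(2:4))
  gm2 <- group_mortality(1L, g2, c(1, 1, 0, 0))
  expect_equal(gm2$mortality, 0.5)
})

test_that("group mortality matches a recount oracle on random partitions", {
  set.seed(61)
  sc <- tiny_cohort(60, seed = 13)
  fm <- fit_feature_pipeline(sc)
  g <- suppressMessages(mapper_network(fm, cover_config(4, 2.1)))
  for (rep in 1:5) {
    memb <- sample(1:3, length(g$members), replace = TRUE)
    gm <- group_mortality(memb, g, sc$event)
    for (k in unique(memb)) {
      pts <- unique(unlist(g$members[memb == k]))
      expect_equal(gm$mortality[gm$group == k], mean(sc$event[pts]))
      expect_equal(gm$n_patients[gm$group == k], length(pts))
    }
  }
})

test_that("greedy merging follows the hand-traced chain example", {
  # disjoint chain A-B-C-D, equal sizes (20 each), mortalities
  # .10/.25/.60/.90
  members <- list(1:20, 21:40, 41:60, 61:80)
  g <- structure(list(
    members = members,
    node_info = data.frame(id = 1:4, cell_x = 1:4, cell_y = 1,
                           size = lengths(members)),
    edges = rbind(c(1L, 2L), c(2L, 3L), c(3L, 4L)),
    n_points = 80, outliers = integer(0)), class = "mapper_graph")
  ev <- integer(80)
  for (i in 1:4) ev[members[[i]][seq_len(c(2, 5, 12, 18)[i])]] <- 1L
  gm <- group_mortality(1:4, g, ev)
  expect_equal(gm$mortality, c(0.10, 0.25, 0.60, 0.90))
  part <- merge_to_three(1:4, g, ev)
  # single merge of (A, B): min |diff| = 0.15, permitted after one cap
  # relaxation (2 x 20 > 1.4 x 80/3)
  expect_equal(nrow(part$merge_trace), 1)
  expect_equal(part$merge_trace$group_a, 1)
  expect_equal(part$merge_trace$group_b, 2)
  expect_equal(part$merge_trace$mortality_diff, 0.15)
  expect_equal(part$group_summary$n_patients, c(40, 20, 20))
  expect_equal(as.character(part$group_summary$phenogroup),
               c("low", "intermediate", "high"))
})

test_that("an initial 3-group partition is returned unchanged", {
  g <- toy_graph(3, rbind(c(1, 2), c(2, 3)),
                 extra_members = list(11:14, 21:24, 31:34))
  ev <- integer(max(unlist(g$members)))
  ev[31:34] <- 1L
  part <- merge_to_three(1:3, g, ev)
  expect_equal(nrow(part$merge_trace), 0)
  expect_equal(length(unique(part$node_to_group)), 3)
})

test_that("ties in mortality difference prefer the smaller combined size", {
  # disjoint chain A-B-C-D with sizes 12/12/10/10; every adjacent pair
  # has |mortality diff| = 0.5, so the tie rule picks the smallest
  # combined pair (C, D)
  members <- list(1:12, 13:24, 25:34, 35:44)
  g <- structure(list(
    members = members,
    node_info = data.frame(id = 1:4, cell_x = 1:4, cell_y = 1,
                           size = lengths(members)),
    edges = rbind(c(1L, 2L), c(2L, 3L), c(3L, 4L)),
    n_points = 44, outliers = integer(0)), class = "mapper_graph")
  ev <- integer(44)
  ev[13:18] <- 1L  # m = 0 / .5 / 0 / .5
  ev[35:39] <- 1L
  gm <- group_mortality(1:4, g, ev)
  expect_equal(gm$mortality, c(0, 0.5, 0, 0.5))
  part <- merge_to_three(1:4, g, ev)
  expect_equal(part$merge_trace$group_a[1], 3)
  expect_equal(part$merge_trace$group_b[1], 4)
})

test_that("merging reduces the group count by exactly one per step", {
  run <- default_run_1000()
  part <- run$partition
  tr <- part$merge_trace
  expect_equal(nrow(tr), part$initial_groups - 3)
  expect_equal(tr$n_groups_after, part$initial_groups - seq_len(nrow(tr)))
  # every executed merge joined adjacent groups: recorded diff is finite
  # and the merged pair existed
  expect_true(all(is.finite(tr$mortality_diff)))
  expect_true(all(tr$group_a < tr$group_b))
})

test_that("every executed merge joins graph-adjacent groups", {
  run <- default_run_1000()
  part <- run$partition
  graph <- run$graph
  memb <- part$autogroups$membership
  for (k in seq_len(nrow(part$merge_trace))) {
    a <- part$merge_trace$group_a[k]
    b <- part$merge_trace$group_b[k]
    ga <- memb[graph$edges[, 1]]
    gb <- memb[graph$edges[, 2]]
    expect_true(any((ga == a & gb == b) | (ga == b & gb == a)))
    memb[memb == b] <- a
  }
})

test_that("patients are uniquely assigned by majority with risk-ward ties", {
  g <- toy_graph(3, rbind(c(1, 2), c(2, 3)))
  ev <- integer(max(unlist(g$members)))
  ev[3] <- 1L  # node 3's private patient dies -> node-3 group = high
  part <- merge_to_three(c(1, 2, 3), g, ev)
  asg <- assign_patients(part, g)
  p2g <- asg$patient_to_group
  # patient 4 is shared between nodes 1 and 2 (groups differ): tie ->
  # higher-mortality group of the two
  m <- part$group_summary
  shared_12 <- p2g[p2g$patient == 4, ]
  expect_equal(shared_12$n_candidate_groups, 2L)
  g1 <- part$node_to_group[1]
  g2 <- part$node_to_group[2]
  want <- if (m$mortality[m$phenogroup == g2] >=
                m$mortality[m$phenogroup == g1]) g2 else g1
  expect_equal(as.character(shared_12$phenogroup), as.character(want))
})

test_that("majority rule and multi-membership match a brute-force scan", {
  run <- default_run_1000()
  part <- run$partition
  graph <- run$graph
  p2g <- part$patient_to_group
  grp <- part$node_to_group
  mort <- setNames(part$group_summary$mortality,
                   as.character(part$group_summary$phenogroup))
  n_multi <- 0
  for (i in sample(seq_len(nrow(p2g)), 150)) {
    p <- p2g$patient[i]
    in_nodes <- which(vapply(graph$members, function(m) p %in% m, TRUE))
    gs <- grp[in_nodes]
    counts <- table(gs)
    counts <- counts[counts > 0]
    top <- names(counts)[counts == max(counts)]
    want <- top[which.max(mort[top])]
    expect_equal(as.character(p2g$phenogroup[i]), want)
    expect_equal(p2g$n_candidate_groups[i], length(unique(as.character(gs))))
  }
  # multi-membership list equals the scan over all patients
  all_multi <- sum(vapply(seq_len(nrow(p2g)), function(i) {
    p <- p2g$patient[i]
    in_nodes <- which(vapply(graph$members, function(m) p %in% m, TRUE))
    length(unique(as.character(grp[in_nodes]))) > 1
  }, TRUE))
  expect_equal(nrow(part$multi_membership), all_multi)
})

test_that("recovered phenogroups have the planted mortality ordering", {
  sc <- default_cohort_1000()
  run <- default_run_1000()
  asg <- run$assignment
  keep <- !is.na(asg$phenogroup)
  planted_hazard <- sim_config()$baseline_hazard_per_group
  mean_hazard <- tapply(planted_hazard[as.character(sc$latent_group[keep])],
                        asg$phenogroup[keep], mean)
  expect_true(all(diff(mean_hazard[c("low", "intermediate", "high")]) > 0))
  gs <- run$partition$group_summary
  expect_true(all(diff(gs$mortality) >= 0))
})
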