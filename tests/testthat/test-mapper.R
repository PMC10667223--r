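test_that("normalized-correlation distance matches hand-worked cases", {
  x <- rbind(c(1, 2, 3), c(2, 4, 6), c(3, 2, 1), c(1, 3, 2))
  d <- normalized_correlation_distance(x)
  expect_equal(d[1, 2], 0)        # perfect correlation
  expect_equal(d[1, 3], 2)        # perfect anticorrelation
  expect_equal(d[1, 4], 0.5)      # Pearson r = 1/2 by hand
  expect_true(isSymmetric(d))
  expect_equal(diag(d), rep(0, 4))
  expect_true(all(d >= 0 & d <= 2))
})

test_that("the distance is invariant to positive affine row transforms", {
  set.seed(11)
  x <- matrix(rnorm(80), 5)
  y <- x
  y[2, ] <- 3.7 * x[2, ] + 12     # positive affine
  y[4, ] <- 0.1 * x[4, ] - 5
  expect_equal(normalized_correlation_distance(y),
               normalized_correlation_distance(x), tolerance = 1e-12)
})

test_that("constant patient rows are rejected with their index", {
  x <- matrix(rnorm(40), 5)
  x[3, ] <- 2
  expect_error(normalized_correlation_distance(x), "3")
})

test_that("classical MDS recovers a line and duplicates collapse", {
  # 3 collinear points: d(1,2) = d(2,3) = 1, d(1,3) = 2
  d <- rbind(c(0, 1, 2), c(1, 0, 1), c(2, 1, 0))
  lens <- mds_lens(d, k = 1)
  expect_equal(sort(as.vector(lens)), c(-1, 0, 1), tolerance = 1e-9)
  # sign convention: largest-magnitude coordinate is positive
  expect_gt(lens[which.max(abs(lens))], 0)
  # duplicate points -> identical lens rows
  set.seed(2)
  x <- matrix(rnorm(50), 5)
  x <- rbind(x, x[2, ])
  lens2 <- suppressMessages(mds_lens(normalized_correlation_distance(x)))
  expect_equal(lens2[6, ], lens2[2, ], tolerance = 1e-9)
})

test_that("MDS reproduces Euclidean-consistent distances", {
  set.seed(3)
  pts <- matrix(rnorm(40), 20, 2)
  d <- as.matrix(dist(pts))
  lens <- mds_lens(d, k = 2)
  expect_equal(as.matrix(dist(lens)), d, tolerance = 1e-8,
               ignore_attr = TRUE)
})

test_that("MDS refuses k beyond the positive spectrum", {
  d <- rbind(c(0, 1, 2), c(1, 0, 1), c(2, 1, 0))  # rank-1 configuration
  expect_error(mds_lens(d, k = 2), "positive eigenvalue")
})

test_that("equalized cover at gain 1 is a quantile partition", {
  set.seed(9)
  lens <- cbind(rnorm(100), rnorm(100))
  cells <- build_cover(lens, cover_config(resolution = 4, gain = 1))
  # project to axis-1 intervals: 4 disjoint bins of 25
  by_ix <- lapply(1:4, function(i) {
    sort(unique(unlist(lapply(cells[vapply(cells, `[[`, 0, "ix") == i],
                              `[[`, "members"))))
  })
  expect_equal(lengths(by_ix), rep(25L, 4))
  expect_equal(sort(unlist(by_ix)), 1:100)
  expect_equal(sum(lengths(by_ix)), 100)  # disjoint
})

test_that("gain 2.1 places the median point in exactly two intervals", {
  # 99 distinct values: the rank-50 point sits at CDF exactly 0.5 and,
  # with width 0.525 intervals, falls in the two centred at 0.375/0.625
  x <- qnorm((1:99) / 100)
  m <- crtphenomap:::interval_membership(
    crtphenomap:::cover_axis_transform(x, TRUE), 4, 2.1)
  expect_equal(which(m[50, ]), c(2L, 3L))
})

test_that("non-equalized gain-1 cover partitions a uniform lens", {
  lens <- cbind(seq(0, 1, length.out = 64), seq(0, 1, length.out = 64))
  cells <- build_cover(lens, cover_config(resolution = 4, gain = 1,
                                          equalized = FALSE))
  all_members <- sort(unlist(lapply(cells, `[[`, "members")))
  expect_equal(all_members, 1:64)  # union covers, no duplicates
})

test_that("every point is covered for any resolution and gain >= 1", {
  set.seed(14)
  lens <- cbind(rt(200, 3), rexp(200))
  for (res in c(1, 3, 7)) {
    for (g in c(1, 1.4, 2.1, 3)) {
      for (eq in c(TRUE, FALSE)) {
        cells <- build_cover(lens, cover_config(res, g, eq))
        expect_equal(sort(unique(unlist(lapply(cells, `[[`, "members")))),
                     1:200)
      }
    }
  }
})

test_that("in-cell clustering follows the histogram-gap heuristic", {
  # singleton cell
  d0 <- matrix(0, 1, 1)
  expect_equal(cluster_cell(1, d0), list(1L))
  # two tight groups at 10x their diameter -> 2 clusters
  pts <- c(0, 0.05, 0.1, 1.0, 1.05, 1.1)
  d <- abs(outer(pts, pts, "-"))
  cl <- cluster_cell(1:6, d)
  expect_equal(length(cl), 2)
  expect_equal(sort(vapply(cl, paste, "", collapse = ",")),
               c("1,2,3", "4,5,6"))
  # equidistant points: no gap, one cluster
  de <- matrix(1, 5, 5)
  diag(de) <- 0
  expect_equal(cluster_cell(1:5, de), list(1:5))
})

test_that("edges are exactly the non-empty pairwise intersections", {
  cells <- list(list(ix = 1, iy = 1, members = c(1L, 2L)),
                list(ix = 2, iy = 1, members = c(2L, 3L)),
                list(ix = 3, iy = 1, members = c(4L, 5L)))
  d <- matrix(0.5, 5, 5)
  diag(d) <- 0
  g <- build_graph(cells, d)
  expect_equal(length(g$members), 3)
  expect_equal(unname(g$edges), rbind(c(1L, 2L)), ignore_attr = TRUE)
  # randomized instances vs O(n^2) oracle
  set.seed(21)
  for (rep in 1:20) {
    memb <- lapply(1:8, function(i) sort(sample(1:15, sample(1:5, 1))))
    want <- matrix(integer(0), 0, 2)
    for (a in 1:8) for (b in 1:8) {
      if (a < b && length(intersect(memb[[a]], memb[[b]]))) {
        want <- rbind(want, c(a, b))
      }
    }
    got <- crtphenomap:::shared_member_edges(memb)
    expect_equal(unname(got), want, ignore_attr = TRUE)
  }
})

test_that("outlier removal keeps the largest component by patients", {
  # two components: nodes {1,2} share 50 patients; node 3 has 3 patients
  cells <- list(list(ix = 1, iy = 1, members = 1:30),
                list(ix = 2, iy = 1, members = 25:50),
                list(ix = 3, iy = 1, members = 51:53))
  d <- matrix(0.5, 53, 53)
  diag(d) <- 0
  g <- remove_outliers(build_graph(cells, d))
  expect_equal(g$outliers, 51:53)
  expect_equal(length(g$members), 2)
  # connected graph -> no outliers
  cells2 <- cells[1:2]
  d2 <- matrix(0.5, 50, 50)
  diag(d2) <- 0
  g2 <- remove_outliers(build_graph(cells2, d2))
  expect_equal(g2$outliers, integer(0))
  # a patient present in both a removed node and a kept node is retained
  # (hand-built graph: the rule is about membership, not connectivity)
  g3 <- structure(list(
    members = list(1:10, c(10L, 11L), c(11L, 12L)),
    node_info = data.frame(id = 1:3, cell_x = 1:3, cell_y = 1,
                           size = c(10L, 2L, 2L)),
    edges = cbind(from = 1L, to = 2L), n_points = 12,
    outliers = integer(0)), class = "mapper_graph")
  g3 <- remove_outliers(g3)
  expect_false(11 %in% g3$outliers)  # also lives in kept node 2
  expect_equal(g3$outliers, 12L)
})

test_that("node coloring is the member event rate", {
  cells <- list(list(ix = 1, iy = 1, members = 1:4),
                list(ix = 2, iy = 1, members = 4:6))
  d <- matrix(0.2, 6, 6)
  diag(d) <- 0
  g <- build_graph(cells, d)
  ev <- c(1, 0, 1, 1, 0, 0)
  g <- color_nodes(g, ev)
  expect_equal(g$node_stats$event_rate, c(0.75, 1 / 3))
  expect_equal(color_nodes(g, rep(0, 6))$node_stats$event_rate, c(0, 0))
  expect_error(color_nodes(g, c(ev[-6], NA)), "without an outcome")
})

test_that("permuting patient order yields an isomorphic graph", {
  set.seed(33)
  x <- matrix(rnorm(25 * 6), 25)
  d <- normalized_correlation_distance(x)
  lens <- suppressMessages(mds_lens(d))
  g1 <- build_graph(build_cover(lens, cover_config(4, 2.1)), d)
  perm <- sample(25)
  xp <- x[perm, ]
  dp <- normalized_correlation_distance(xp)
  lensp <- suppressMessages(mds_lens(dp))
  g2 <- build_graph(build_cover(lensp, cover_config(4, 2.1)), dp)
  # map g2 members back to original labels and compare signatures
  back <- lapply(g2$members, function(m) sort(perm[m]))
  s1 <- graph_signature(g1$members, g1$edges)
  s2 <- graph_signature(back, g2$edges)
  expect_identical(s1$nodes, s2$nodes)
  expect_identical(s1$edges, s2$edges)
})

test_that("the full construction matches the brute-force enumerator", {
  set.seed(55)
  for (rep in 1:12) {
    n <- sample(8:30, 1)
    p <- sample(3:6, 1)
    x <- matrix(rnorm(n * p), n)
    res <- sample(2:4, 1)
    gain <- sample(c(1, 1.5, 2.1), 1)
    eq <- sample(c(TRUE, FALSE), 1)
    d <- normalized_correlation_distance(x)
    lens <- suppressMessages(mds_lens(d))
    graph <- build_graph(build_cover(lens, cover_config(res, gain, eq)), d)
    oracle <- oracle_mapper(x, res, gain, eq)
    expect_same_mapper(graph, oracle)
  }
})

test_that("graph exports round-trip node membership", {
  sc <- tiny_cohort(30, seed = 5)
  fm <- fit_feature_pipeline(sc)
  g <- suppressMessages(mapper_network(fm, cover_config(4, 2.1),
                                       event = sc$event))
  f1 <- tempfile(fileext = ".graphml")
  f2 <- tempfile(fileext = ".json")
  export_mapper_graphml(g, f1)
  export_mapper_json(g, f2)
  gg <- igraph::read_graph(f1, format = "graphml")
  expect_equal(igraph::vcount(gg), length(g$members))
  js <- jsonlite::read_json(f2, simplifyVector = FALSE)
  expect_equal(length(js$nodes), length(g$members))
  unlink(c(f1, f2))
})
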