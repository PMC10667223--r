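#' Normalized-correlation distance between patients
#'
#' `d(i, j) = 1 - r(i, j)`, where `r` is the Pearson correlation between
#' the two patients' feature rows (each row centered and scaled across
#' the 16 features).  Distances lie in `[0, 2]` and are invariant to
#' positive affine transforms of a patient row.
#'
#' @param x Numeric matrix (patients x features), no missing values,
#'   at least 2 feature columns.
#' @return Symmetric distance matrix with zero diagonal.
#' @export
normalized_correlation_distance <- function(x) {
  if (ncol(x) < 2) stop("need at least 2 feature columns", call. = FALSE)
  if (anyNA(x)) stop("feature matrix must not contain missing values",
                     call. = FALSE)
  row_sd <- apply(x, 1, stats::sd)
  flat <- row_sd < .Machine$double.eps^0.5
  if (any(flat)) {
    stop("patient row(s) with zero variance across features: ",
         paste(which(flat), collapse = ", "), call. = FALSE)
  }
  d <- 1 - stats::cor(t(x))
  d <- pmin(pmax(d, 0), 2)
  diag(d) <- 0
  dimnames(d) <- NULL
  d
}

#' Classical multidimensional-scaling lens
#'
#' Torgerson MDS: double-center `-0.5 * J %*% D^2 %*% J`, take the top-k
#' eigenpairs with positive eigenvalues, and scale eigenvectors by the
#' square root of their eigenvalues.  Sign convention: each axis is
#' oriented so that its largest-magnitude coordinate is positive (first
#' such coordinate on ties), making the lens fully deterministic.
#' Negative eigenvalues (the distance not being Euclidean-embeddable)
#' are dropped with a message.
#'
#' @param d Symmetric distance matrix.
#' @param k Number of lens axes (default 2).
#' @return n x k matrix of lens coordinates.
#' @export
mds_lens <- function(d, k = 2) {
  n <- nrow(d)
  d2 <- d^2
  rm <- rowMeans(d2)
  b <- -0.5 * (sweep(sweep(d2, 1, rm), 2, rm) + mean(d2))
  e <- eigen(b, symmetric = TRUE)
  tol <- max(abs(e$values[1]), 1) * 1e-10
  n_pos <- sum(e$values > tol)
  if (n_pos < k) {
    stop("only ", n_pos, " positive eigenvalue(s); reduce k (requested ",
         k, ")", call. = FALSE)
  }
  if (any(e$values < -tol)) {
    message("mds_lens: dropping ", sum(e$values < -tol),
            " negative eigenvalue(s) (distance is non-Euclidean)")
  }
  coords <- e$vectors[, seq_len(k), drop = FALSE] %*%
    diag(sqrt(e$values[seq_len(k)]), k)
  for (j in seq_len(k)) {
    i0 <- which.max(abs(coords[, j]))
    if (coords[i0, j] < 0) coords[, j] <- -coords[, j]
  }
  coords
}

#' Cover configuration
#'
#' @param resolution Number of base intervals per lens axis (default 25).
#' @param gain Interval expansion factor (default 2.1); adjacent
#'   intervals overlap by a fraction `1 - 1/gain` of their width.
#' @param equalized Use the empirical-CDF (rank) transform per axis
#'   before uniform binning (default `TRUE`); otherwise a linear min-max
#'   transform.
#' @return An object of class `cover_config`.
#' @export
cover_config <- function(resolution = 25, gain = 2.1, equalized = TRUE) {
  if (resolution < 1) stop("resolution must be >= 1", call. = FALSE)
  if (gain < 1) stop("gain must be >= 1", call. = FALSE)
  structure(list(resolution = as.integer(resolution), gain = gain,
                 equalized = isTRUE(equalized)),
            class = "cover_config")
}

# axis transform to [0, 1]: mid-rank empirical CDF (ties: average ranks)
# when equalized, min-max otherwise
cover_axis_transform <- function(x, equalized) {
  if (equalized) {
    (rank(x, ties.method = "average") - 0.5) / length(x)
  } else {
    r <- max(x) - min(x)
    if (r == 0) rep(0.5, length(x)) else (x - min(x)) / r
  }
}

# membership of transformed values in the expanded intervals:
# interval i has center (i - 0.5)/R and width gain/R; intervals are
# closed on the left and open on the right (the last is closed) so that
# gain = 1 yields a disjoint partition
interval_membership <- function(t, resolution, gain) {
  half <- gain / (2 * resolution)
  m <- matrix(FALSE, length(t), resolution)
  for (i in seq_len(resolution)) {
    ctr <- (i - 0.5) / resolution
    lo <- ctr - half
    hi <- ctr + half
    m[, i] <- if (i == resolution) t >= lo & t <= hi else t >= lo & t < hi
  }
  m
}

#' Build the 2-D cover over the lens space
#'
#' Each lens axis is transformed to `[0, 1]` (empirical CDF when
#' equalized), divided into `resolution` equal-width base intervals,
#' each expanded about its center to width `gain / resolution`.  A cover
#' cell is the Cartesian product of one interval per axis; empty cells
#' are dropped.  With `gain >= 1` every point belongs to at least one
#' cell.
#'
#' @param lens n x 2 lens matrix from [mds_lens()].
#' @param cfg A [cover_config()].
#' @return List of cells in axis-1-major order, each
#'   `list(ix, iy, members)` with `members` the point indices.
#' @export
build_cover <- function(lens, cfg = cover_config()) {
  stopifnot(ncol(lens) == 2, all(is.finite(lens)))
  mx <- interval_membership(
    cover_axis_transform(lens[, 1], cfg$equalized), cfg$resolution, cfg$gain)
  my <- interval_membership(
    cover_axis_transform(lens[, 2], cfg$equalized), cfg$resolution, cfg$gain)
  cells <- list()
  for (i in seq_len(cfg$resolution)) {
    in_i <- mx[, i]
    if (!any(in_i)) next
    for (j in seq_len(cfg$resolution)) {
      members <- which(in_i & my[, j])
      if (length(members)) {
        cells[[length(cells) + 1]] <- list(ix = i, iy = j, members = members)
      }
    }
  }
  cells
}

#' Cluster the patients of one cover cell into Mapper nodes
#'
#' Single-linkage clustering on the restricted distance submatrix, cut
#' by the histogram-gap heuristic: merge heights are binned into `bins`
#' equal-width bins over `[0, max height]`, and the dendrogram is cut at
#' the lower edge of the first empty bin occurring after mass has
#' appeared (an all-empty prefix is not a gap, so e.g. equidistant
#' points form one cluster).  No gap, a singleton cell, or all-zero
#' heights yield a single cluster.
#'
#' @param members Point indices of the cell.
#' @param d Full distance matrix.
#' @param bins Number of histogram bins (default 10).
#' @return List of integer vectors (clusters of point indices).
#' @export
cluster_cell <- function(members, d, bins = 10) {
  m <- length(members)
  if (m == 0) stop("empty cell", call. = FALSE)
  if (m == 1) return(list(members))
  hc <- stats::hclust(stats::as.dist(d[members, members, drop = FALSE]),
                      method = "single")
  cutoff <- gap_cutoff(hc$height, bins)
  if (!is.finite(cutoff)) return(list(members))
  cl <- stats::cutree(hc, h = cutoff)
  lapply(unname(split(seq_len(m), cl)), function(i) members[i])
}

# histogram-gap heuristic on merge heights; returns Inf when no gap
gap_cutoff <- function(heights, bins) {
  hmax <- max(heights)
  if (hmax <= 0) return(Inf)
  breaks <- seq(0, hmax, length.out = bins + 1)
  idx <- findInterval(heights, breaks, rightmost.closed = TRUE)
  counts <- tabulate(idx, nbins = bins)
  first_filled <- which(counts > 0)[1]
  gaps <- which(counts == 0)
  gaps <- gaps[gaps > first_filled]
  if (!length(gaps)) return(Inf)
  breaks[gaps[1]]
}

#' Assemble the Mapper graph from per-cell clusters
#'
#' One node per cluster (ids in cell-major order); an edge joins two
#' nodes iff they share at least one patient; no self-loops.
#'
#' @param cells Cover cells from [build_cover()].
#' @param d Distance matrix.
#' @param bins Histogram bins for [cluster_cell()].
#' @return An object of class `mapper_graph`: `members` (list of
#'   patient-index vectors per node), `node_info` (data frame: id, cell
#'   indices, size), `edges` (2-column matrix of node ids),
#'   `n_points`.
#' @export
build_graph <- function(cells, d, bins = 10) {
  members <- list()
  info <- list()
  for (cell in cells) {
    for (cl in cluster_cell(cell$members, d, bins)) {
      members[[length(members) + 1]] <- cl
      info[[length(info) + 1]] <-
        data.frame(cell_x = cell$ix, cell_y = cell$iy, size = length(cl))
    }
  }
  node_info <- do.call(rbind, info)
  node_info <- cbind(id = seq_along(members), node_info)
  graph <- structure(
    list(members = members, node_info = node_info,
         edges = shared_member_edges(members), n_points = nrow(d),
         outliers = integer(0)),
    class = "mapper_graph")
  graph
}

shared_member_edges <- function(members) {
  # invert membership: patient -> node ids, then connect co-occurring nodes
  pt <- unlist(members, use.names = FALSE)
  nd <- rep(seq_along(members), lengths(members))
  by_pt <- split(nd, pt)
  pairs <- unique(do.call(rbind, lapply(by_pt, function(ns) {
    if (length(ns) < 2) return(NULL)
    ns <- sort(ns)
    t(utils::combn(ns, 2))
  })))
  if (is.null(pairs)) pairs <- matrix(integer(0), 0, 2)
  colnames(pairs) <- c("from", "to")
  pairs[order(pairs[, 1], pairs[, 2]), , drop = FALSE]
}

#' Convert a Mapper graph to an igraph object
#'
#' Edge weight = number of shared patients; node attributes carry size,
#' originating cover cell, member ids and, if present, event rates.
#'
#' @param graph A `mapper_graph`.
#' @return An `igraph` graph.
#' @export
as_igraph_mapper <- function(graph) {
  n <- length(graph$members)
  w <- apply(graph$edges, 1, function(e) {
    length(intersect(graph$members[[e[1]]], graph$members[[e[2]]]))
  })
  g <- igraph::make_empty_graph(n, directed = FALSE)
  if (nrow(graph$edges)) {
    g <- igraph::add_edges(g, t(graph$edges))
    igraph::E(g)$weight <- w
  }
  igraph::V(g)$size <- graph$node_info$size
  igraph::V(g)$cell_x <- graph$node_info$cell_x
  igraph::V(g)$cell_y <- graph$node_info$cell_y
  igraph::V(g)$members <- vapply(graph$members, paste, "", collapse = ",")
  if (!is.null(graph$node_stats)) {
    igraph::V(g)$event_rate <- graph$node_stats$event_rate
  }
  g
}

#' Remove outlier components
#'
#' Keeps the connected component containing the most patients (ties:
#' most nodes, then lowest node id).  Patients appearing only in removed
#' nodes are recorded as outliers; a patient also present in the main
#' component is retained.
#'
#' @param graph A `mapper_graph`.
#' @return The pruned `mapper_graph`, with `outliers` (patient indices)
#'   and `removed_nodes` filled in; node ids are renumbered and the
#'   original ids kept in `node_info$orig_id`.
#' @export
remove_outliers <- function(graph) {
  n <- length(graph$members)
  if (n == 0) stop("empty graph", call. = FALSE)
  g <- igraph::make_empty_graph(n, directed = FALSE)
  if (nrow(graph$edges)) g <- igraph::add_edges(g, t(graph$edges))
  comp <- igraph::components(g)$membership
  stats_by_comp <- lapply(seq_len(max(comp)), function(k) {
    nodes <- which(comp == k)
    list(nodes = nodes,
         n_patients = length(unique(unlist(graph$members[nodes]))),
         n_nodes = length(nodes), min_id = min(nodes))
  })
  np <- vapply(stats_by_comp, `[[`, 0, "n_patients")
  nn <- vapply(stats_by_comp, `[[`, 0, "n_nodes")
  mi <- vapply(stats_by_comp, `[[`, 0, "min_id")
  best <- order(-np, -nn, mi)[1]
  keep <- stats_by_comp[[best]]$nodes
  kept_patients <- unique(unlist(graph$members[keep]))
  all_patients <- unique(unlist(graph$members))
  out <- structure(graph, class = "mapper_graph")
  out$removed_nodes <- setdiff(seq_len(n), keep)
  out$outliers <- sort(setdiff(all_patients, kept_patients))
  out$members <- graph$members[keep]
  out$node_info <- graph$node_info[keep, , drop = FALSE]
  out$node_info$orig_id <- out$node_info$id
  out$node_info$id <- seq_along(keep)
  rownames(out$node_info) <- NULL
  remap <- match(seq_len(n), keep)
  e <- graph$edges
  e <- e[e[, 1] %in% keep & e[, 2] %in% keep, , drop = FALSE]
  e[, 1] <- remap[e[, 1]]
  e[, 2] <- remap[e[, 2]]
  out$edges <- e
  out
}

#' Color nodes by outcome
#'
#' Per-node event rate: deaths among members / members.
#'
#' @param graph A `mapper_graph`.
#' @param event Integer 0/1 vector indexed by patient (cohort row).
#' @return The graph with `node_stats` (id, n_members, n_events,
#'   event_rate) attached.
#' @export
color_nodes <- function(graph, event) {
  stats <- lapply(seq_along(graph$members), function(i) {
    ev <- event[graph$members[[i]]]
    if (anyNA(ev)) {
      stop("node ", i, " has member(s) without an outcome", call. = FALSE)
    }
    data.frame(id = i, n_members = length(ev), n_events = sum(ev),
               event_rate = mean(ev))
  })
  graph$node_stats <- do.call(rbind, stats)
  graph
}

#' Build the full topological network from a feature matrix
#'
#' Distance -> two MDS lenses -> cover -> per-cell single-linkage
#' clustering -> shared-member edges -> outlier-component removal.
#'
#' @param features Z-scored feature matrix (patients x features).
#' @param cover A [cover_config()].
#' @param bins Histogram bins for the in-cell clustering cut.
#' @param event Optional 0/1 outcome vector for node coloring.
#' @return A `mapper_graph` with `lens` and `cover` recorded.
#' @export
mapper_network <- function(features, cover = cover_config(), bins = 10,
                           event = NULL) {
  d <- normalized_correlation_distance(features)
  lens <- mds_lens(d, k = 2)
  cells <- build_cover(lens, cover)
  graph <- build_graph(cells, d, bins)
  graph <- remove_outliers(graph)
  graph$lens <- lens
  graph$cover <- cover
  if (!is.null(event)) graph <- color_nodes(graph, event)
  graph
}

#' @export
print.mapper_graph <- function(x, ...) {
  cat("Mapper graph:", length(x$members), "nodes,", nrow(x$edges),
      "edges,", length(unique(unlist(x$members))), "patients retained,",
      length(x$outliers), "outliers\n")
  invisible(x)
}

#' Export a Mapper graph
#'
#' @param graph A `mapper_graph`.
#' @param file Output path.
#' @export
export_mapper_graphml <- function(graph, file) {
  igraph::write_graph(as_igraph_mapper(graph), file, format = "graphml")
  invisible(file)
}

#' @rdname export_mapper_graphml
#' @export
export_mapper_json <- function(graph, file) {
  obj <- list(
    nodes = lapply(seq_along(graph$members), function(i) {
      nd <- list(id = i, cell = c(graph$node_info$cell_x[i],
                                  graph$node_info$cell_y[i]),
                 members = graph$members[[i]])
      if (!is.null(graph$node_stats)) {
        nd$event_rate <- graph$node_stats$event_rate[i]
      }
      nd
    }),
    edges = apply(graph$edges, 1, function(e) c(e[1], e[2]),
                  simplify = FALSE),
    outliers = graph$outliers
  )
  jsonlite::write_json(obj, file, auto_unbox = TRUE, digits = NA)
  invisible(file)
}
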