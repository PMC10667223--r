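# Independent brute-force Mapper construction: naive loops throughout,
# sharing no code with the package implementation.  Used to verify the
# full network construction on small random instances.

oracle_pearson_distance <- function(x) {
  n <- nrow(x)
  d <- matrix(0, n, n)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      a <- x[i, ] - mean(x[i, ])
      b <- x[j, ] - mean(x[j, ])
      r <- sum(a * b) / sqrt(sum(a^2) * sum(b^2))
      d[i, j] <- min(max(1 - r, 0), 2)
    }
  }
  diag(d) <- 0
  d
}

oracle_mds <- function(d, k = 2) {
  n <- nrow(d)
  d2 <- d^2
  b <- matrix(0, n, n)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      b[i, j] <- -0.5 * (d2[i, j] - mean(d2[i, ]) - mean(d2[, j]) +
                           mean(d2))
    }
  }
  e <- eigen((b + t(b)) / 2, symmetric = TRUE)
  coords <- matrix(0, n, k)
  for (j in seq_len(k)) {
    coords[, j] <- e$vectors[, j] * sqrt(e$values[j])
    i0 <- 1
    for (i in seq_len(n)) if (abs(coords[i, j]) > abs(coords[i0, j])) i0 <- i
    if (coords[i0, j] < 0) coords[, j] <- -coords[, j]
  }
  coords
}

oracle_axis_transform <- function(x, equalized) {
  n <- length(x)
  if (equalized) {
    out <- numeric(n)
    for (i in seq_len(n)) {
      below <- sum(x < x[i])
      ties <- sum(x == x[i])
      r <- below + (ties + 1) / 2  # average rank
      out[i] <- (r - 0.5) / n
    }
    out
  } else {
    if (max(x) == min(x)) rep(0.5, n)
    else (x - min(x)) / (max(x) - min(x))
  }
}

oracle_in_interval <- function(t, i, resolution, gain) {
  ctr <- (i - 0.5) / resolution
  half <- gain / (2 * resolution)
  if (i == resolution) t >= ctr - half && t <= ctr + half
  else t >= ctr - half && t < ctr + half
}

# single linkage merge heights = naive agglomeration (min inter-cluster
# distance at every step)
oracle_single_linkage_heights <- function(d) {
  clusters <- as.list(seq_len(nrow(d)))
  heights <- numeric(0)
  while (length(clusters) > 1) {
    best <- c(NA, NA)
    best_d <- Inf
    for (a in seq_along(clusters)) {
      for (b in seq_along(clusters)) {
        if (a < b) {
          dd <- Inf
          for (i in clusters[[a]]) for (j in clusters[[b]]) {
            dd <- min(dd, d[i, j])
          }
          if (dd < best_d) {
            best_d <- dd
            best <- c(a, b)
          }
        }
      }
    }
    heights <- c(heights, best_d)
    clusters[[best[1]]] <- c(clusters[[best[1]]], clusters[[best[2]]])
    clusters[[best[2]]] <- NULL
  }
  heights
}

oracle_gap_cut <- function(heights, bins = 10) {
  hmax <- max(heights)
  if (hmax <= 0) return(Inf)
  breaks <- seq(0, hmax, length.out = bins + 1)
  counts <- integer(bins)
  for (h in heights) {
    for (b in seq_len(bins)) {
      hi_ok <- if (b == bins) h <= breaks[b + 1] else h < breaks[b + 1]
      if (h >= breaks[b] && hi_ok) {
        counts[b] <- counts[b] + 1
        break
      }
    }
  }
  seen_mass <- FALSE
  for (b in seq_len(bins)) {
    if (counts[b] > 0) seen_mass <- TRUE
    else if (seen_mass) return(breaks[b])
  }
  Inf
}

# connected components of the threshold graph d <= cut (single-linkage
# clusters at that height)
oracle_threshold_components <- function(members, d, cut) {
  m <- length(members)
  comp <- seq_len(m)
  repeat {
    changed <- FALSE
    for (i in seq_len(m)) {
      for (j in seq_len(m)) {
        if (i != j && d[members[i], members[j]] <= cut &&
            comp[i] != comp[j]) {
          comp[comp == max(comp[i], comp[j])] <- min(comp[i], comp[j])
          changed <- TRUE
        }
      }
    }
    if (!changed) break
  }
  lapply(unique(comp), function(cc) members[comp == cc])
}

oracle_cluster_cell <- function(members, d, bins = 10) {
  if (length(members) == 1) return(list(members))
  sub <- d[members, members, drop = FALSE]
  heights <- oracle_single_linkage_heights(sub)
  cut <- oracle_gap_cut(heights, bins)
  if (!is.finite(cut)) return(list(members))
  oracle_threshold_components(members, d, cut)
}

# full brute-force Mapper graph on a raw feature matrix; returns node
# member sets and the edge list (as pairs of node indices)
oracle_mapper <- function(x, resolution, gain, equalized, bins = 10) {
  d <- oracle_pearson_distance(x)
  lens <- oracle_mds(d, 2)
  t1 <- oracle_axis_transform(lens[, 1], equalized)
  t2 <- oracle_axis_transform(lens[, 2], equalized)
  nodes <- list()
  for (i in seq_len(resolution)) {
    for (j in seq_len(resolution)) {
      members <- integer(0)
      for (p in seq_len(nrow(x))) {
        if (oracle_in_interval(t1[p], i, resolution, gain) &&
            oracle_in_interval(t2[p], j, resolution, gain)) {
          members <- c(members, p)
        }
      }
      if (length(members)) {
        for (cl in oracle_cluster_cell(members, d, bins)) {
          nodes[[length(nodes) + 1]] <- sort(cl)
        }
      }
    }
  }
  edges <- matrix(integer(0), 0, 2)
  for (a in seq_along(nodes)) {
    for (b in seq_along(nodes)) {
      if (a < b && length(intersect(nodes[[a]], nodes[[b]])) > 0) {
        edges <- rbind(edges, c(a, b))
      }
    }
  }
  list(nodes = nodes, edges = edges)
}

# canonical signatures for comparing two mapper graphs irrespective of
# node numbering: sorted multiset of node member sets, and sorted
# multiset of edges written as member-set signature pairs
graph_signature <- function(nodes, edges) {
  sig <- vapply(nodes, function(m) paste(sort(m), collapse = ","), "")
  esig <- if (nrow(edges)) {
    apply(edges, 1, function(e) {
      paste(sort(c(sig[e[1]], sig[e[2]])), collapse = " | ")
    })
  } else {
    character(0)
  }
  list(nodes = sort(sig), edges = sort(esig))
}
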