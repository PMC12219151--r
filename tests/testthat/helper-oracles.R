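# Independent brute-force oracles used by the property tests.  These are
# deliberately naive (quadratic / exhaustive) implementations kept apart
# from the package's own code paths.

# single-linkage CpG chaining by transitive closure of the pairwise
# "within max_gap" relation (connected components of an adjacency graph)
oracle_chain_regions <- function(pos, max_gap, min_cpgs) {
  n <- length(pos)
  if (n == 0) return(list())
  adj <- abs(outer(pos, pos, "-")) <= max_gap
  comp <- seq_len(n)
  repeat {
    changed <- FALSE
    for (i in seq_len(n)) for (j in seq_len(n)) {
      if (adj[i, j] && comp[j] != comp[i]) {
        comp[comp == comp[j]] <- comp[i]
        changed <- TRUE
      }
    }
    if (!changed) break
  }
  out <- split(pos, comp)
  Filter(function(x) length(x) >= min_cpgs, unname(out))
}

# all-pairs interval merge until fixed point; intervals as 2-col matrix
# (0-based half-open); touching intervals merge (as GRanges reduce does)
oracle_merge_intervals <- function(iv) {
  iv <- iv[order(iv[, 1]), , drop = FALSE]
  repeat {
    merged <- FALSE
    i <- 1
    while (i < nrow(iv)) {
      if (iv[i + 1, 1] <= iv[i, 2]) {      # overlap or touch
        iv[i, 2] <- max(iv[i, 2], iv[i + 1, 2])
        iv <- iv[-(i + 1), , drop = FALSE]
        merged <- TRUE
      } else i <- i + 1
    }
    if (!merged) break
  }
  iv
}

# naive overlap test between two half-open intervals
oracle_overlaps <- function(a_start, a_end, b_start, b_end) {
  a_start < b_end & b_start < a_end
}

# Benjamini-Hochberg by the hand formula
oracle_bh <- function(p) {
  n <- length(p)
  o <- order(p)
  adj <- p[o] * n / seq_len(n)
  adj <- rev(cummin(rev(adj)))
  adj <- pmin(adj, 1)
  out <- numeric(n)
  out[o] <- adj
  out
}

# exact two-sided Wilcoxon rank-sum p by exhaustive enumeration of all
# C(m+n, m) group assignments (no ties assumed)
oracle_wilcoxon_exact <- function(x, y) {
  m <- length(x); n <- length(y)
  r <- rank(c(x, y))
  u_obs <- sum(r[seq_len(m)]) - m * (m + 1) / 2
  combos <- utils::combn(m + n, m)
  all_r <- rank(c(x, y))           # same values, all arrangements of labels
  u_all <- apply(combos, 2, function(idx) {
    sum(all_r[idx]) - m * (m + 1) / 2
  })
  min(1, 2 * min(mean(u_all <= u_obs), mean(u_all >= u_obs)))
}

# hypergeometric upper tail by direct summation
oracle_fisher_upper <- function(overlap, set_size, selected, universe) {
  ks <- overlap:min(set_size, selected)
  sum(choose(set_size, ks) * choose(universe - set_size, selected - ks)) /
    choose(universe, selected)
}

# O(n^3)-style naive agglomeration with average linkage on a distance
# matrix; returns the merge heights in order
oracle_average_linkage_heights <- function(d) {
  d <- as.matrix(d)
  clusters <- as.list(seq_len(nrow(d)))
  heights <- numeric(0)
  while (length(clusters) > 1) {
    best <- c(NA, NA); best_h <- Inf
    for (i in seq_along(clusters)) for (j in seq_along(clusters)) {
      if (i < j) {
        h <- mean(d[clusters[[i]], clusters[[j]]])
        if (h < best_h) { best_h <- h; best <- c(i, j) }
      }
    }
    heights <- c(heights, best_h)
    clusters[[best[1]]] <- c(clusters[[best[1]]], clusters[[best[2]]])
    clusters[[best[2]]] <- NULL
  }
  heights
}
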