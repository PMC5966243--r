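# Independent brute-force oracles used to cross-check the package's
# statistical routines. These deliberately use naive enumeration, never the
# code paths they validate.

# Exact two-sided Mann-Whitney p by enumerating every assignment of the
# pooled values to the two arms (tie-free values assumed).
oracle_mwu <- function(a, b) {
  pooled <- c(a, b)
  na <- length(a)
  u_of <- function(x, y) sum(outer(x, y, ">")) + 0.5 * sum(outer(x, y, "=="))
  idx <- utils::combn(length(pooled), na)
  us <- apply(idx, 2, function(i) u_of(pooled[i], pooled[-i]))
  u_obs <- u_of(a, b)
  total <- ncol(idx)
  p <- 2 * min(sum(us <= u_obs), sum(us >= u_obs)) / total
  list(u = u_obs, p = min(1, p))
}

# geNorm M by direct pairwise-SD arithmetic.
oracle_genorm_m <- function(expr) {
  k <- ncol(expr)
  vapply(seq_len(k), function(j) {
    mean(vapply(setdiff(seq_len(k), j), function(l) {
      stats::sd(expr[, j] - expr[, l])
    }, numeric(1)))
  }, numeric(1))
}

# Exact conditional p for a 2 x c table by enumerating all tables with the
# observed margins and summing probabilities <= the observed table's.
oracle_exact_2xc <- function(tab) {
  stopifnot(nrow(tab) == 2)
  col_tot <- colSums(tab)
  r1 <- sum(tab[1, ])
  n <- sum(tab)
  log_prob <- function(row1) {
    sum(lchoose(col_tot, row1)) - lchoose(n, r1)
  }
  rows <- expand.grid(lapply(col_tot, function(ct) 0:ct))
  rows <- rows[rowSums(rows) == r1, , drop = FALSE]
  probs <- exp(apply(rows, 1, log_prob))
  p_obs <- exp(log_prob(tab[1, ]))
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

# Exhaustive Ward merge oracle: at every step evaluate the exact increase
# in total within-cluster sum of squares for every candidate merge and take
# the minimum. Returns the sequence of merged member sets and heights on
# the sqrt(2 * delta-SS) scale used by Euclidean-input Ward trees.
oracle_ward <- function(points) {
  ss <- function(idx) {
    sub <- points[idx, , drop = FALSE]
    sum(sweep(sub, 2, colMeans(sub))^2)
  }
  clusters <- lapply(seq_len(nrow(points)), identity)
  merges <- list()
  heights <- numeric()
  while (length(clusters) > 1) {
    best <- NULL
    best_delta <- Inf
    for (i in seq_len(length(clusters) - 1)) {
      for (j in seq(i + 1, length(clusters))) {
        delta <- ss(c(clusters[[i]], clusters[[j]])) -
          ss(clusters[[i]]) - ss(clusters[[j]])
        if (delta < best_delta) {
          best_delta <- delta
          best <- c(i, j)
        }
      }
    }
    merged <- sort(c(clusters[[best[1]]], clusters[[best[2]]]))
    merges[[length(merges) + 1]] <- merged
    heights <- c(heights, sqrt(2 * best_delta))
    clusters <- c(clusters[-best], list(merged))
  }
  list(merges = merges, heights = heights)
}

# Member sets at each merge of an hclust tree, sorted for comparison.
hclust_merge_sets <- function(hc) {
  sets <- vector("list", nrow(hc$merge))
  for (i in seq_len(nrow(hc$merge))) {
    members <- unlist(lapply(hc$merge[i, ], function(node) {
      if (node < 0) -node else sets[[node]]
    }))
    sets[[i]] <- sort(members)
  }
  sets
}
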