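# Independent oracles and fixture builders used across the suite.
# Everything here is deliberately naive (brute force, enumeration) and
# independent of the package's own implementations.

# --- spanning-tree enumeration -------------------------------------------
# decode a Pruefer sequence over labels 1..n into the edge list of its tree
prufer_decode <- function(seq, n) {
  degree <- rep(1L, n)
  for (s in seq) degree[s] <- degree[s] + 1L
  edges <- matrix(0L, 0L, 2L)
  for (s in seq) {
    leaf <- which(degree == 1L)[1L]
    edges <- rbind(edges, c(min(leaf, s), max(leaf, s)))
    degree[leaf] <- degree[leaf] - 1L
    degree[s] <- degree[s] - 1L
  }
  last <- which(degree == 1L)
  rbind(edges, c(min(last), max(last)))
}

# minimum total weight over ALL spanning trees of the complete graph on
# `coords` (n^(n-2) trees via Pruefer sequences); n <= 7 keeps this feasible
brute_force_mst_weight <- function(coords) {
  n <- nrow(coords)
  d <- as.matrix(stats::dist(coords))
  if (n == 2L) return(d[1, 2])
  seqs <- as.matrix(expand.grid(rep(list(seq_len(n)), n - 2L)))
  best <- Inf
  for (r in seq_len(nrow(seqs))) {
    ed <- prufer_decode(seqs[r, ], n)
    w <- sum(d[ed])
    if (w < best) best <- w
  }
  best
}

# --- KNN by exhaustive distance comparison --------------------------------
brute_force_knn_edges <- function(coords, k) {
  n <- nrow(coords)
  d <- as.matrix(stats::dist(coords))
  pairs <- matrix(0L, 0L, 2L)
  for (i in seq_len(n)) {
    ord <- setdiff(order(d[i, ], seq_len(n)), i)[seq_len(k)]
    pairs <- rbind(pairs, cbind(pmin(i, ord), pmax(i, ord)))
  }
  unique(pairs[order(pairs[, 1], pairs[, 2]), , drop = FALSE])
}

# --- dense grid minimization of the fit objective -------------------------
# Staged full-grid search: a full grid at each step size, each stage
# restricted to a window of +/- 1.5x the previous step around the previous
# minimum.  The objective is convex, so the true minimizer lies within one
# coarse cell of the coarse grid minimizer and staged refinement locates it
# to the finest step.  The objective value is computed directly from its
# formula here, independent of the package's evaluator and solver.
grid_oracle <- function(dataset, graph, penalties, lower, upper,
                        steps = c(0.25, 0.05, 0.01)) {
  n <- nrow(dataset$coords)
  p <- ncol(dataset$predictors)
  nb <- n * p
  X <- dataset$predictors
  y <- dataset$response
  ei <- graph$edges[, 1]
  ej <- graph$edges[, 2]
  gw <- if (is.null(penalties$group_weight)) sqrt(n) else
    penalties$group_weight
  idx <- function(i, k) (k - 1L) * n + i  # column-major beta layout
  batch_objective <- function(P) {  # P: N x nb, one beta vector per row
    vals <- numeric(nrow(P))
    for (i in seq_len(n)) {
      fit_i <- rep(0, nrow(P))
      for (k in seq_len(p)) fit_i <- fit_i + X[i, k] * P[, idx(i, k)]
      vals <- vals + (y[i] - fit_i)^2 / n
    }
    for (k in seq_len(p)) {
      for (e in seq_along(ei)) {
        vals <- vals + penalties$lambda1 *
          abs(P[, idx(ei[e], k)] - P[, idx(ej[e], k)])
      }
      sq <- rep(0, nrow(P))
      for (i in seq_len(n)) sq <- sq + P[, idx(i, k)]^2
      vals <- vals + penalties$lambda3 * gw * sqrt(sq)
    }
    vals + penalties$lambda2 * rowSums(abs(P))
  }
  centre <- rep((lower + upper) / 2, nb)
  half <- rep((upper - lower) / 2, nb)
  for (s in steps) {
    grids <- lapply(seq_len(nb), function(jj) {
      g <- seq(centre[jj] - half[jj], centre[jj] + half[jj], by = s)
      pmin(pmax(g, lower), upper)
    })
    pts <- as.matrix(expand.grid(grids))
    centre <- pts[which.min(batch_objective(pts)), ]
    half <- rep(1.5 * s, nb)
  }
  matrix(centre, n, p)
}

# --- pair-counting Rand agreement over all C(n,2) pairs -------------------
brute_force_ari <- function(a, b) {
  n <- length(a)
  same_a <- outer(a, a, "==")[upper.tri(diag(n))]
  same_b <- outer(b, b, "==")[upper.tri(diag(n))]
  n11 <- sum(same_a & same_b)
  n00 <- sum(!same_a & !same_b)
  n10 <- sum(same_a & !same_b)
  n01 <- sum(!same_a & same_b)
  total <- n11 + n00 + n10 + n01
  expected <- (n11 + n10) * (n11 + n01) / total
  maxi <- ((n11 + n10) + (n11 + n01)) / 2
  if (maxi == expected) return(if (n11 == expected) 1 else 0)
  (n11 - expected) / (maxi - expected)
}

# --- misc fixtures --------------------------------------------------------
rdirichlet1 <- function(n, alpha) {
  g <- matrix(stats::rgamma(n * length(alpha), shape = alpha), n,
              length(alpha), byrow = TRUE)
  g / rowSums(g)
}

# two tight, well-separated point clouds
two_clouds <- function(n_per = 20, gap = 10, seed = 1) {
  set.seed(seed)
  coords <- rbind(cbind(stats::rnorm(n_per, 0, 0.1),
                        stats::rnorm(n_per, 0, 0.1)),
                  cbind(stats::rnorm(n_per, gap, 0.1),
                        stats::rnorm(n_per, gap, 0.1)))
  list(coords = coords, labels = rep(1:2, each = n_per))
}

# small aligned dataset files on disk (dense text), ids shuffled per file
write_toy_files <- function(dir, ids = c("A", "B", "C"), seed = 1) {
  set.seed(seed)
  n <- length(ids)
  coords <- data.frame(id = ids, x = seq_len(n), y = 0)
  resp <- data.frame(id = rev(ids), value = seq_len(n))
  pred <- data.frame(id = sample(ids), g1 = c(1, 2, 3)[seq_len(n)],
                     g2 = c(4, 0, 6)[seq_len(n)])
  cp <- file.path(dir, "coords.tsv")
  rp <- file.path(dir, "resp.tsv")
  pp <- file.path(dir, "pred.tsv")
  utils::write.table(coords, cp, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  utils::write.table(resp, rp, sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(pred, pp, sep = "\t", quote = FALSE, row.names = FALSE)
  list(coords = cp, response = rp, predictors = pp, pred_table = pred)
}
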