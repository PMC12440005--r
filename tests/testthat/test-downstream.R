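test_that("attribution constraints hold exactly on arbitrary inputs", {
  # negative coefficients shrink to zero
  v <- matrix(c(-0.3, 0.5), 1, 2)
  p <- matrix(c(0.4, 0.6), 1, 2)
  expect_equal(apply_attribution_constraints(v, p),
               matrix(c(0, 0.5), 1, 2))
  # absent cell type contributes nothing
  v2 <- matrix(c(1, 1), 1, 2)
  p2 <- matrix(c(0, 0.5), 1, 2)
  expect_equal(apply_attribution_constraints(v2, p2),
               matrix(c(0, 1), 1, 2))
  # property sweep
  set.seed(77)
  for (rep in 1:20) {
    v <- matrix(rnorm(50), 10, 5)
    p <- matrix(runif(50) * rbinom(50, 1, 0.7), 10, 5)
    out <- apply_attribution_constraints(v, p)
    expect_true(all(out >= 0))
    expect_true(all(out[p == 0] == 0))
    # untouched where legal
    legal <- v > 0 & p > 0
    expect_equal(out[legal], v[legal])
  }
})

test_that("attribution recovers a single-cell-type generative signal", {
  ok_level <- 0L
  ok_sparse <- 0L
  for (rep in 1:10) {
    set.seed(300 + rep)
    n <- 200
    co <- cbind(runif(n), runif(n))
    props <- rdirichlet1(n, c(2, 2, 2))
    colnames(props) <- c("t1", "t2", "t3")
    expr <- props[, 1] * 2.0 + rnorm(n, 0, 0.05)
    af <- suppressWarnings(
      attribute_celltypes(expr, props, co, gene = "target",
                          seed = 300 + rep))
    m1 <- mean(af$values[, "t1"])
    if (is.finite(m1) && m1 > 1.6 && m1 < 2.4) ok_level <- ok_level + 1L
    if (mean(af$values[, "t2"] > 0) <= 0.1 &&
        mean(af$values[, "t3"] > 0) <= 0.1) ok_sparse <- ok_sparse + 1L
  }
  expect_gte(ok_level, 9L)
  expect_gte(ok_sparse, 9L)
})

test_that("attribution refuses under-determined and invalid inputs", {
  co <- cbind(runif(4), runif(4))
  props <- rdirichlet1(4, rep(1, 5))
  expect_error(attribute_celltypes(rnorm(4), props, co),
               "under-determined")
  bad <- matrix(c(0.5, 1.2, 0.1, 0.4, 0.2, 0.1, 0.3, 0.2), 4, 2)
  expect_error(attribute_celltypes(rnorm(4), bad, co), "\\[0, 1\\]")
})

test_that("Moran's I matches closed-form path-graph values and is affine-invariant", {
  g <- build_knn_graph(cbind(0:3, 0), k = 1)
  expect_equal(morans_i(c(1, 2, 3, 4), g, 99)$statistic, 0.4)
  expect_equal(morans_i(c(1, -1, 1, -1), g, 99)$statistic, -1)
  expect_error(morans_i(rep(2, 4), g, 99), "constant")
  # affine invariance: a*x + b leaves I unchanged for a > 0
  set.seed(8)
  co <- cbind(runif(30), runif(30))
  gg <- build_mst(co)
  v <- rnorm(30)
  expect_equal(morans_i(v, gg, 99)$statistic,
               morans_i(3 * v + 7, gg, 99)$statistic)
  # p-value floor
  mr <- morans_i(v, gg, n_permutations = 99, seed = 4)
  expect_gte(mr$perm_pvalue, 1 / 100)
})

test_that("Moran's I agrees with an independent implementation", {
  skip_if_not_installed("ape")
  set.seed(12)
  co <- cbind(runif(25), runif(25))
  g <- suppressWarnings(build_knn_graph(co, 3))
  v <- rnorm(25)
  W <- as.matrix(row_standardized_weights(g))
  expect_equal(morans_i(v, g, 99)$statistic,
               ape::Moran.I(v, W)$observed, tolerance = 1e-12)
})

test_that("SVG detection flags smooth gradients and not i.i.d. noise", {
  set.seed(14)
  n <- 80
  co <- cbind(runif(n), runif(n))
  g <- suppressWarnings(build_spatial_graph(co))
  flag_grad <- 0L
  flag_noise <- 0L
  for (rep in 1:10) {
    set.seed(400 + rep)
    grad <- co[, 1] + rnorm(n, 0, sqrt(var(co[, 1]) / 10))  # SNR 10
    noise <- rnorm(n)
    vals <- cbind(gradient = grad, iid = noise, silent = rep(0, n))
    out <- detect_svgs(vals, g, alpha = 0.05, n_permutations = 999,
                       seed = 400 + rep)
    # the all-zero column is skipped entirely
    expect_false("silent" %in% out$celltype)
    if (out$is_svg[out$celltype == "gradient"]) flag_grad <- flag_grad + 1L
    if (out$is_svg[out$celltype == "iid"]) flag_noise <- flag_noise + 1L
  }
  expect_gte(flag_grad, 9L)
  expect_lte(flag_noise, 1L)
})

test_that("covariation tests reproduce hand-computed Spearman values", {
  # rank-identical vectors
  set.seed(15)
  a <- matrix(rnorm(30), 30, 1, dimnames = list(NULL, "gA"))
  out <- covariation_test(a, a^3 + 1, c("C1", "C2"), n_permutations = 99)
  expect_equal(out$rho, 1)
  # hand example: ranks (1,2,3) vs (3,1,2) -> rho = -0.5
  b1 <- matrix(c(1, 2, 3), 3, 1, dimnames = list(NULL, "g1"))
  b2 <- matrix(c(3, 1, 2), 3, 1, dimnames = list(NULL, "g2"))
  out2 <- covariation_test(b1, b2, c("C1", "C2"), n_permutations = 99)
  expect_equal(out2$rho, -0.5)
  # agreement with stats::cor on random fields
  set.seed(16)
  fa <- matrix(rnorm(200), 40, 5, dimnames = list(NULL, paste0("a", 1:5)))
  fb <- matrix(rnorm(200), 40, 5, dimnames = list(NULL, paste0("b", 1:5)))
  out3 <- covariation_test(fa, fb, c("C1", "C2"), n_permutations = 99)
  ref <- cor(fa, fb, method = "spearman")
  expect_equal(out3$rho,
               ref[cbind(match(out3$gene1, rownames(ref)),
                         match(out3$gene2, colnames(ref)))],
               tolerance = 1e-12)
  # monotone-transform invariance
  out4 <- covariation_test(exp(fa), fb, c("C1", "C2"), n_permutations = 99)
  expect_equal(out3$rho, out4$rho, tolerance = 1e-12)
})

test_that("covariation bookkeeping: skips, same-celltype canonical pairs, errors", {
  set.seed(18)
  fa <- matrix(rnorm(60), 20, 3, dimnames = list(NULL, c("g1", "g2", "g3")))
  fa[, 2] <- 0
  fa[1, 2] <- 5  # only 1 nonzero spot -> skipped
  out <- covariation_test(fa, fa, c("C1", "C1"), n_permutations = 99)
  expect_false(any(out$gene1 == "g2" | out$gene2 == "g2"))
  # same cell type: only canonical pairs, no self-pairs
  expect_true(all(out$gene1 < out$gene2))
  expect_error(covariation_test(fa, fa[1:10, ], c("C1", "C2")),
               "spot axis")
})

test_that("tensor aggregation averages per-section counts and applies replication", {
  mk <- function(sig) {
    data.frame(celltype1 = "ductal", celltype2 = "caf",
               gene1 = paste0("g", seq_along(sig)),
               gene2 = paste0("h", seq_along(sig)),
               rho = 0.5, perm_pvalue = 0.001, fdr = 0.01,
               passes_effect_size = TRUE, significant = sig)
  }
  s1 <- mk(c(TRUE, TRUE, TRUE, FALSE, FALSE))
  s2 <- mk(c(TRUE, TRUE, TRUE, TRUE, TRUE))
  tens <- aggregate_tensors(list(sec1 = s1, sec2 = s2), min_sections = 2)
  # counts 3 and 5 -> strength 4
  expect_equal(tens$interaction_strength["ductal", "caf"], 4)
  # pairs significant in both sections replicate; single-section ones do not
  expect_equal(nrow(tens$replicated), 3)
  expect_true(all(tens$replicated$n_sections == 2))
  # binary tensors are 0/1
  expect_true(all(unlist(tens$binary) %in% c(0L, 1L)))
  # mirrored association is stored once
  s3 <- s1[1, ]
  s3[, c("celltype1", "celltype2", "gene1", "gene2")] <-
    c("caf", "ductal", "h1", "g1")
  s3$significant <- TRUE
  tens2 <- aggregate_tensors(list(sec1 = s1, sec2 = rbind(s2, s3)),
                             min_sections = 2)
  expect_equal(sum(tens2$binary$sec2), 5)
  # universe mismatch errors without the explicit flag
  s4 <- mk(TRUE)
  s4$gene1 <- "unseen"
  expect_error(aggregate_tensors(list(a = s1, b = s4)), "universe")
  expect_no_error(aggregate_tensors(list(a = s1, b = s4),
                                    intersect_universe = TRUE))
})

test_that("context features form valid compositions and recover spatial niches", {
  # all cells the same type -> one-hot composition rows
  set.seed(19)
  co <- cbind(runif(40), runif(40))
  cf <- build_context_features(co, rep("T", 40), k_neighbors = 5,
                               k_niches = 2, seed = 1)
  expect_true(all(cf$local_composition == 1))
  expect_equal(unname(rowSums(cf$local_composition)), rep(1, 40))
  expect_equal(unname(rowSums(cf$niche_indicators)), rep(1L, 40))
  # two separated regions with disjoint type mixes -> niches = regions
  tc <- two_clouds(n_per = 30, gap = 50)
  types <- c(sample(c("A", "B"), 30, replace = TRUE),
             sample(c("C", "D"), 30, replace = TRUE))
  cf2 <- build_context_features(tc$coords, types, k_neighbors = 10,
                                k_niches = 2, seed = 2)
  expect_equal(adjusted_rand_index(cf2$niche_labels, tc$labels), 1)
  expect_equal(unname(rowSums(cf2$local_composition)), rep(1, 60))
  expect_error(build_context_features(co, rep("T", 40), k_neighbors = 40),
               "k_neighbors")
})
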