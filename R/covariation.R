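rank_standardize <- function(m) {
  # Pearson on these columns = Spearman on the originals
  r <- apply(m, 2, rank)
  sds <- apply(r, 2, stats::sd)
  sds[sds == 0] <- NA
  scale(r, center = TRUE, scale = sds)
}

#' Cross-cell-type gene covariation test
#'
#' For two cell types C1 and C2 with attributed coefficient fields over the
#' same spots, computes for every gene pair (G1, G2) the Spearman
#' correlation across spots between the C1 field of G1 and the C2 field of
#' G2, assesses two-sided significance by permuting the spot order of one
#' field, applies Benjamini-Hochberg correction across all tested pairs of
#' this cell-type pair, and flags a pair significant iff its FDR is below
#' `fdr_alpha` and `|rho|` reaches `effect_threshold`. Genes nonzero in
#' fewer than 3 spots (or with tied-constant ranks) are skipped. When the
#' two cell types are the same, only canonical pairs G1 < G2 are tested.
#'
#' One seeded set of spot permutations is shared by all gene pairs, which
#' lets the null be computed as matrix products; each pair still sees
#' uniformly random permutations.
#'
#' @param fieldsA,fieldsB numeric spots x genes matrices of attributed
#'   coefficients for cell types C1 and C2 (colnames = gene names).
#' @param celltype_pair character vector of the two cell-type names.
#' @param n_permutations permutations (default 999).
#' @param effect_threshold minimum `|rho|` (default 0.3).
#' @param fdr_alpha FDR level (default 0.05).
#' @param seed integer seed.
#' @return data.frame of class `covariation_result` with columns
#'   `celltype1`, `celltype2`, `gene1`, `gene2`, `rho`, `perm_pvalue`,
#'   `fdr`, `passes_effect_size`, `significant`.
#' @export
covariation_test <- function(fieldsA, fieldsB,
                             celltype_pair = c("C1", "C2"),
                             n_permutations = 999, effect_threshold = 0.3,
                             fdr_alpha = 0.05, seed = 1L) {
  fieldsA <- as.matrix(fieldsA)
  fieldsB <- as.matrix(fieldsB)
  if (nrow(fieldsA) != nrow(fieldsB))
    stop("the two field matrices must share the spot axis (",
         nrow(fieldsA), " vs ", nrow(fieldsB), " rows)")
  if (!is.null(rownames(fieldsA)) && !is.null(rownames(fieldsB)) &&
      !identical(rownames(fieldsA), rownames(fieldsB)))
    stop("the two field matrices must share the spot axis (row names differ)")
  n <- nrow(fieldsA)
  if (is.null(colnames(fieldsA)))
    colnames(fieldsA) <- paste0("g", seq_len(ncol(fieldsA)))
  if (is.null(colnames(fieldsB)))
    colnames(fieldsB) <- paste0("g", seq_len(ncol(fieldsB)))

  usable <- function(m) {
    ok <- colSums(m != 0) >= 3
    ok & apply(m, 2, function(v) length(unique(v)) > 1)
  }
  keepA <- usable(fieldsA)
  keepB <- usable(fieldsB)
  empty <- data.frame(celltype1 = character(), celltype2 = character(),
                      gene1 = character(), gene2 = character(),
                      rho = numeric(), perm_pvalue = numeric(),
                      fdr = numeric(), passes_effect_size = logical(),
                      significant = logical())
  if (!any(keepA) || !any(keepB)) return(structure(empty, class = c("covariation_result", "data.frame")))

  RA <- rank_standardize(fieldsA[, keepA, drop = FALSE])
  RB <- rank_standardize(fieldsB[, keepB, drop = FALSE])
  rho <- crossprod(RA, RB) / (n - 1)

  set.seed(seed)
  exceed <- matrix(0L, ncol(RA), ncol(RB))
  for (b in seq_len(n_permutations)) {
    idx <- sample.int(n)
    rb <- crossprod(RA[idx, , drop = FALSE], RB) / (n - 1)
    exceed <- exceed + (abs(rb) >= abs(rho))
  }
  pval <- (1 + exceed) / (n_permutations + 1)

  same <- identical(celltype_pair[1], celltype_pair[2])
  ga <- colnames(fieldsA)[keepA]
  gb <- colnames(fieldsB)[keepB]
  out <- data.frame(celltype1 = celltype_pair[1], celltype2 = celltype_pair[2],
                    gene1 = rep(ga, times = length(gb)),
                    gene2 = rep(gb, each = length(ga)),
                    rho = as.vector(rho), perm_pvalue = as.vector(pval),
                    stringsAsFactors = FALSE)
  if (same) out <- out[out$gene1 < out$gene2, , drop = FALSE]
  out$fdr <- stats::p.adjust(out$perm_pvalue, method = "BH")
  out$passes_effect_size <- abs(out$rho) >= effect_threshold
  out$significant <- out$fdr < fdr_alpha & out$passes_effect_size
  rownames(out) <- NULL
  structure(out, class = c("covariation_result", "data.frame"))
}

canonical_pair_key <- function(df) {
  a <- paste(df$celltype1, df$gene1, sep = "\r")
  b <- paste(df$celltype2, df$gene2, sep = "\r")
  swap <- b < a
  key_a <- ifelse(swap, b, a)
  key_b <- ifelse(swap, a, b)
  list(key = paste(key_a, key_b, sep = "\n"),
       celltype1 = ifelse(swap, df$celltype2, df$celltype1),
       gene1 = ifelse(swap, df$gene2, df$gene1),
       celltype2 = ifelse(swap, df$celltype1, df$celltype2),
       gene2 = ifelse(swap, df$gene1, df$gene2))
}

#' Aggregate per-section covariation results into interaction tensors
#'
#' Binarizes each section's tested associations into a 4-way array over
#' (gene1, gene2, celltype1, celltype2) — 1 = significant, 0 = otherwise —
#' after canonical ordering (an association and its mirror are stored once).
#' A pair is *replicated* if significant in at least `min_sections`
#' sections. The interaction strength of a cell-type pair is the arithmetic
#' mean over sections of its count of significant gene pairs.
#'
#' @param section_results named list (one element per section) of
#'   [covariation_test()] tables, each possibly spanning several cell-type
#'   pairs (rbind them).
#' @param min_sections sections required for replication (default 2).
#' @param intersect_universe if the sections' gene / cell-type universes
#'   differ, restrict to their intersection instead of erroring (default
#'   FALSE).
#' @return list of class `covariation_tensor`: `binary` (list of per-section
#'   4-way arrays), `aggregated_counts` (celltype x celltype x section
#'   array), `interaction_strength` (celltype x celltype matrix),
#'   `replicated` (data.frame of replicated pairs with `n_sections`),
#'   `min_sections`.
#' @export
aggregate_tensors <- function(section_results, min_sections = 2,
                              intersect_universe = FALSE) {
  stopifnot(length(section_results) >= 1)
  if (is.null(names(section_results)))
    names(section_results) <- paste0("section", seq_along(section_results))

  genes_of <- function(df) sort(unique(c(df$gene1, df$gene2)))
  cts_of <- function(df) sort(unique(c(df$celltype1, df$celltype2)))
  gene_sets <- lapply(section_results, genes_of)
  ct_sets <- lapply(section_results, cts_of)
  same_universe <- all(vapply(gene_sets, identical, logical(1),
                              gene_sets[[1]])) &&
    all(vapply(ct_sets, identical, logical(1), ct_sets[[1]]))
  if (!same_universe && !intersect_universe)
    stop("sections have different gene/cell-type universes; pass ",
         "`intersect_universe = TRUE` to restrict to the intersection")
  genes <- Reduce(intersect, gene_sets)
  cts <- Reduce(intersect, ct_sets)

  binary <- list()
  counts <- array(0, dim = c(length(cts), length(cts),
                             length(section_results)),
                  dimnames = list(cts, cts, names(section_results)))
  sig_keys <- list()
  key_info <- list()
  for (s in names(section_results)) {
    df <- section_results[[s]]
    df <- df[df$gene1 %in% genes & df$gene2 %in% genes &
               df$celltype1 %in% cts & df$celltype2 %in% cts, , drop = FALSE]
    can <- canonical_pair_key(df)
    arr <- array(0L, dim = c(length(genes), length(genes), length(cts),
                             length(cts)),
                 dimnames = list(genes, genes, cts, cts))
    sig <- which(df$significant)
    # keep one entry per canonical association
    first <- !duplicated(can$key)
    idx <- which(first & df$significant)
    if (length(idx)) {
      arr[cbind(match(can$gene1[idx], genes), match(can$gene2[idx], genes),
                match(can$celltype1[idx], cts),
                match(can$celltype2[idx], cts))] <- 1L
      tab <- as.matrix(table(factor(can$celltype1[idx], levels = cts),
                             factor(can$celltype2[idx], levels = cts)))
      # canonical ordering fills one triangle; report symmetrically
      sym <- tab + t(tab)
      diag(sym) <- diag(tab)
      counts[, , s] <- sym
    }
    binary[[s]] <- arr
    sig_keys[[s]] <- unique(can$key[idx])
    ki <- data.frame(key = can$key, celltype1 = can$celltype1,
                     gene1 = can$gene1, celltype2 = can$celltype2,
                     gene2 = can$gene2, stringsAsFactors = FALSE)
    key_info[[s]] <- ki[!duplicated(ki$key), , drop = FALSE]
  }

  strength <- apply(counts, c(1, 2), mean)
  all_keys <- unlist(sig_keys, use.names = FALSE)
  key_counts <- table(all_keys)
  rep_keys <- names(key_counts)[key_counts >= min_sections]
  info <- unique(do.call(rbind, key_info))
  rep_df <- info[match(rep_keys, info$key), c("celltype1", "gene1",
                                              "celltype2", "gene2"),
                 drop = FALSE]
  rep_df$n_sections <- as.integer(key_counts[rep_keys])
  rownames(rep_df) <- NULL
  structure(list(binary = binary, aggregated_counts = counts,
                 interaction_strength = strength, replicated = rep_df,
                 min_sections = as.integer(min_sections)),
            class = "covariation_tensor")
}

#' @export
print.covariation_tensor <- function(x, ...) {
  cat("covariation_tensor: ", length(x$binary), " sections, ",
      nrow(x$replicated), " replicated pairs (min_sections = ",
      x$min_sections, ")\n", sep = "")
  invisible(x)
}

#' Local neighborhood composition and niche context features
#'
#' For each cell, computes the relative cell-type frequencies among its
#' `k_neighbors` nearest neighbors (Euclidean, self excluded) — the local
#' composition vector — then clusters all composition vectors by k-means
#' into `k_niches` niches and returns one-hot niche indicators. Composition
#' columns and niche indicators are designed to sit alongside gene-level
#' predictors in a single predictor matrix.
#'
#' @param coords numeric n x 2 coordinates.
#' @param celltype_labels length-n character/factor cell-type labels.
#' @param k_neighbors neighbors per cell (default 30); must be < n.
#' @param k_niches number of niches (default 5); at least 2.
#' @param seed integer seed for the k-means.
#' @return list of class `context_features`: `local_composition` (n x T,
#'   rows sum to 1), `niche_labels` (integer in 1..k_niches),
#'   `niche_indicators` (n x k_niches one-hot, columns `niche_1..`).
#' @export
build_context_features <- function(coords, celltype_labels, k_neighbors = 30,
                                   k_niches = 5, seed = 1L) {
  coords <- as.matrix(coords)
  n <- nrow(coords)
  k_neighbors <- as.integer(k_neighbors)
  k_niches <- as.integer(k_niches)
  if (k_neighbors >= n) stop("`k_neighbors` must be smaller than n")
  if (k_niches < 2L) stop("`k_niches` must be at least 2")
  celltype_labels <- as.character(celltype_labels)
  stopifnot(length(celltype_labels) == n)
  types <- sort(unique(celltype_labels))
  d <- as.matrix(stats::dist(coords))
  comp <- matrix(0, n, length(types), dimnames = list(rownames(coords), types))
  for (i in seq_len(n)) {
    others <- setdiff(seq_len(n), i)
    nb <- others[order(d[i, others], others)][seq_len(k_neighbors)]
    tt <- table(factor(celltype_labels[nb], levels = types))
    comp[i, ] <- as.numeric(tt) / k_neighbors
  }
  set.seed(seed)
  km <- stats::kmeans(comp, centers = min(k_niches, nrow(unique(comp))),
                      nstart = 10L, iter.max = 100L)
  labels <- km$cluster
  onehot <- matrix(0L, n, max(labels),
                   dimnames = list(rownames(coords),
                                   paste0("niche_", seq_len(max(labels)))))
  onehot[cbind(seq_len(n), labels)] <- 1L
  structure(list(local_composition = comp, niche_labels = labels,
                 niche_indicators = onehot),
            class = "context_features")
}
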