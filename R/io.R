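delim_for <- function(path) {
  if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
}

read_table_checked <- function(path, what) {
  if (!file.exists(path)) stop(what, " file not found: ", path)
  utils::read.table(path, header = TRUE, sep = delim_for(path),
                    stringsAsFactors = FALSE, check.names = FALSE,
                    comment.char = "")
}

# coerce a character column to numeric, reporting the offending cells
numeric_checked <- function(x, what, ids = NULL) {
  v <- suppressWarnings(as.numeric(x))
  bad <- which(is.na(v) & !is.na(x))
  if (length(bad)) {
    where <- if (is.null(ids)) paste("row", bad[1]) else ids[bad[1]]
    stop("non-numeric value ", shQuote(x[bad[1]]), " in ", what,
         " at ", where)
  }
  v
}

#' Read an aligned spatial dataset from delimited files
#'
#' Loads coordinates, a response and a predictor matrix, aligning the three
#' by spot identifier (never by row order) and imposing a deterministic row
#' order (sorted spot id). Dense text (TSV/CSV, by extension) and Matrix
#' Market sparse triplets (`.mtx` with `<path>.rows` / `<path>.cols` name
#' sidecars) are interchangeable for the predictor matrix and produce
#' identical datasets for identical content. After alignment, the prevalence
#' filter of `options$min_expression_fraction` is applied to the predictors.
#'
#' Expected layouts: coordinates with columns `id, x, y`; response with
#' columns `id, value`; dense predictors with spot ids in the first column
#' (orientation `"spots_by_genes"`) or predictor names in the first column
#' and spot ids as headers (`"genes_by_spots"`), declared explicitly via
#' `options$orientation`, never autodetected.
#'
#' @param coords_path,response_path,predictors_path input files.
#' @param options a [run_config()].
#' @return a [spatial_dataset()].
#' @export
read_spatial_dataset <- function(coords_path, response_path, predictors_path,
                                 options = run_config()) {
  co <- read_table_checked(coords_path, "coordinates")
  if (ncol(co) < 3L) stop("coordinates file needs columns id, x, y")
  co_ids <- as.character(co[[1]])
  if (anyDuplicated(co_ids))
    stop("duplicate spot ids in coordinates: ",
         paste(unique(co_ids[duplicated(co_ids)]), collapse = ", "))
  coords <- cbind(numeric_checked(co[[2]], "coordinates", co_ids),
                  numeric_checked(co[[3]], "coordinates", co_ids))
  rownames(coords) <- co_ids

  re <- read_table_checked(response_path, "response")
  if (ncol(re) < 2L) stop("response file needs columns id, value")
  re_ids <- as.character(re[[1]])
  if (anyDuplicated(re_ids))
    stop("duplicate spot ids in response: ",
         paste(unique(re_ids[duplicated(re_ids)]), collapse = ", "))
  response <- numeric_checked(re[[2]], "response", re_ids)
  names(response) <- re_ids

  pr <- read_predictor_matrix(predictors_path, options$orientation)

  ids <- sort(co_ids)
  align <- function(have, what) {
    missing <- setdiff(ids, have)
    extra <- setdiff(have, ids)
    if (length(missing))
      stop(what, " file is missing spot id(s): ",
           paste(missing, collapse = ", "))
    if (length(extra))
      stop(what, " file has unknown spot id(s): ",
           paste(extra, collapse = ", "))
  }
  align(re_ids, "response")
  align(rownames(pr), "predictors")

  predictors <- pr[ids, , drop = FALSE]
  if (options$log1p_expression) {
    if (any(predictors < 0))
      stop("log1p transform requested but predictors contain negatives")
    predictors <- log1p(predictors)
  }
  filt <- filter_low_prevalence(predictors, colnames(predictors),
                                options$min_expression_fraction)
  spatial_dataset(coords[ids, , drop = FALSE], response[ids], filt$matrix,
                  spot_ids = ids, predictor_names = filt$names)
}

read_predictor_matrix <- function(path, orientation) {
  if (grepl("\\.mtx$", path, ignore.case = TRUE)) {
    if (!file.exists(path)) stop("predictors file not found: ", path)
    rows_path <- paste0(path, ".rows")
    cols_path <- paste0(path, ".cols")
    if (!file.exists(rows_path) || !file.exists(cols_path))
      stop("Matrix Market input needs name sidecars ", rows_path, " and ",
           cols_path)
    m <- as.matrix(Matrix::readMM(path))
    rn <- readLines(rows_path)
    cn <- readLines(cols_path)
    if (nrow(m) != length(rn) || ncol(m) != length(cn))
      stop("sidecar name lengths do not match the .mtx dimensions")
    dimnames(m) <- list(rn, cn)
  } else {
    tb <- read_table_checked(path, "predictors")
    rn <- as.character(tb[[1]])
    if (anyDuplicated(rn))
      stop("duplicate row ids in predictors: ",
           paste(unique(rn[duplicated(rn)]), collapse = ", "))
    m <- as.matrix(tb[, -1, drop = FALSE])
    if (!is.numeric(m)) {
      for (jj in seq_len(ncol(m)))
        m[, jj] <- numeric_checked(m[, jj], "predictors", rn)
      storage.mode(m) <- "double"
    }
    rownames(m) <- rn
  }
  if (orientation == "genes_by_spots") m <- t(m)
  m
}

#' Drop predictors observed in too few spots
#'
#' A predictor (gene) is kept iff it is nonzero in at least `min_fraction`
#' of spots; the boundary is inclusive, so with `min_fraction = 0.10` a gene
#' nonzero in exactly 10% of spots is retained. Survivor order is preserved
#' and the operation is idempotent.
#'
#' @param predictors numeric n x p matrix.
#' @param names length-p predictor names.
#' @param min_fraction required nonzero fraction in `[0, 1]`.
#' @return list with elements `matrix` and `names` (survivors only).
#' @export
filter_low_prevalence <- function(predictors, names = colnames(predictors),
                                  min_fraction = 0.10) {
  predictors <- as.matrix(predictors)
  stopifnot(min_fraction >= 0, min_fraction <= 1)
  if (is.null(names)) names <- paste0("x", seq_len(ncol(predictors)))
  keep <- colMeans(predictors != 0) >= min_fraction
  if (!any(keep))
    stop("no predictors survive the prevalence filter (min_fraction = ",
         min_fraction, ")")
  m <- predictors[, keep, drop = FALSE]
  colnames(m) <- names[keep]
  list(matrix = m, names = names[keep])
}

#' Write / read a coefficient field as delimited text
#'
#' The `"long"` layout emits `(spot_id, predictor, coefficient)` rows,
#' omitting exact zeros; `"dense"` emits the full n x p table with a
#' `spot_id` column. Values are serialized with 15 significant digits, so a
#' write/read round trip reproduces the field to better than 1e-10.
#'
#' @param field numeric n x p matrix with spot ids as rownames and predictor
#'   names as colnames (e.g. the `field` of an `svc_fit`).
#' @param path output file (TSV/CSV by extension).
#' @param layout `"long"` or `"dense"`.
#' @return invisibly, the path.
#' @export
write_coefficient_field <- function(field, path, layout = c("long", "dense")) {
  layout <- match.arg(layout)
  field <- as.matrix(field)
  if (is.null(rownames(field)))
    rownames(field) <- paste0("s", seq_len(nrow(field)))
  if (is.null(colnames(field)))
    colnames(field) <- paste0("x", seq_len(ncol(field)))
  sep <- delim_for(path)
  fmt <- function(v) sprintf("%.15g", v)
  if (layout == "long") {
    nz <- which(field != 0, arr.ind = TRUE)
    df <- data.frame(spot_id = rownames(field)[nz[, 1]],
                     predictor = colnames(field)[nz[, 2]],
                     coefficient = fmt(field[nz]),
                     stringsAsFactors = FALSE)
    df <- df[order(df$spot_id, df$predictor), , drop = FALSE]
  } else {
    df <- data.frame(spot_id = rownames(field),
                     apply(field, 2, fmt), check.names = FALSE,
                     stringsAsFactors = FALSE)
  }
  utils::write.table(df, path, sep = sep, quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_coefficient_field
#' @param spot_ids,predictor_names for `"long"` input, the full universe of
#'   spots and predictors (zeros are not stored in that layout); defaults to
#'   the ids present in the file.
#' @return `read_coefficient_field` returns the n x p numeric matrix.
#' @export
read_coefficient_field <- function(path, spot_ids = NULL,
                                   predictor_names = NULL) {
  tb <- read_table_checked(path, "coefficient field")
  if (identical(names(tb)[1:3], c("spot_id", "predictor", "coefficient")) &&
      ncol(tb) == 3L) {
    if (is.null(spot_ids)) spot_ids <- sort(unique(as.character(tb$spot_id)))
    if (is.null(predictor_names))
      predictor_names <- sort(unique(as.character(tb$predictor)))
    m <- matrix(0, length(spot_ids), length(predictor_names),
                dimnames = list(spot_ids, predictor_names))
    m[cbind(match(as.character(tb$spot_id), spot_ids),
            match(as.character(tb$predictor), predictor_names))] <-
      numeric_checked(tb$coefficient, "coefficient field")
    m
  } else {
    ids <- as.character(tb[[1]])
    m <- as.matrix(tb[, -1, drop = FALSE])
    storage.mode(m) <- "double"
    rownames(m) <- ids
    m
  }
}

#' Write a sparse predictor matrix as Matrix Market triplets
#'
#' Companion to [read_spatial_dataset()]: writes `path` (.mtx) plus the
#' `<path>.rows` and `<path>.cols` name sidecars.
#'
#' @param m numeric matrix with dimnames.
#' @param path output `.mtx` path.
#' @return invisibly, the path.
#' @export
write_predictor_mtx <- function(m, path) {
  Matrix::writeMM(methods::as(methods::as(Matrix::Matrix(as.matrix(m),
                                                         sparse = TRUE),
                                          "generalMatrix"), "TsparseMatrix"),
                  path)
  writeLines(rownames(m), paste0(path, ".rows"))
  writeLines(colnames(m), paste0(path, ".cols"))
  invisible(path)
}

#' Write a reproducibility manifest for a run
#'
#' Records the configuration, seed and MD5 checksums of every input file so
#' a run can be re-executed bit-for-bit for its deterministic stages.
#'
#' @param path output JSON path.
#' @param config a [run_config()] (or any list of settings).
#' @param seed integer seed of the run.
#' @param inputs character vector of input file paths to checksum.
#' @param extra optional named list of additional settings to record.
#' @return invisibly, the path.
#' @export
write_run_manifest <- function(path, config, seed, inputs = character(),
                               extra = list()) {
  inputs <- as.character(unlist(inputs))
  sums <- if (length(inputs)) as.list(tools::md5sum(inputs)) else list()
  manifest <- list(package = "spatfuse",
                   version = as.character(utils::packageVersion("spatfuse")),
                   seed = as.integer(seed),
                   config = unclass(config),
                   input_md5 = sums,
                   extra = extra)
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA)
  invisible(path)
}
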