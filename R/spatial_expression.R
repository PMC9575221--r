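#' Spatial expression objects
#'
#' A `spatial_expression` bundles a gene-by-spot expression matrix with the
#' 2-D slide coordinates of its spots. Coordinates are continuous values in
#' arbitrary slide units; all distances downstream are Euclidean in those
#' units.
#'
#' @param values Gene-by-spot matrix (base or `Matrix` sparse), non-negative
#'   and finite, with row and column names.
#' @param coords Data frame with columns `spot_id`, `x`, `y`; one row per
#'   matrix column.
#' @return An object of class `spatial_expression` with elements `values`
#'   (a `dgCMatrix`), `coords` (tibble), `gene_ids` and `spot_ids`.
#' @examples
#' m <- matrix(c(1, 0, 2, 3), 2, 2,
#'   dimnames = list(c("A", "B"), c("s1", "s2"))
#' )
#' st <- spatial_expression(m, data.frame(spot_id = c("s1", "s2"), x = 0:1, y = 0))
#' st
#' @export
spatial_expression <- function(values, coords) {
  if (is.null(rownames(values)) || is.null(colnames(values))) {
    abort("expression matrix must have gene row names and spot column names")
  }
  values <- methods::as(methods::as(Matrix::Matrix(values, sparse = TRUE), "CsparseMatrix"), "generalMatrix")
  if (any(values@x < 0) || any(!is.finite(values@x))) {
    abort("expression values must be non-negative and finite")
  }
  coords <- as_tibble(coords)
  need <- c("spot_id", "x", "y")
  if (!all(need %in% names(coords))) {
    abort("coords must have columns spot_id, x, y")
  }
  coords$spot_id <- as.character(coords$spot_id)
  if (anyDuplicated(coords$spot_id) > 0) abort("duplicated spot_ids in coords")
  if (!setequal(coords$spot_id, colnames(values))) {
    abort("coords spot_ids do not match expression matrix columns")
  }
  coords <- coords[match(colnames(values), coords$spot_id), need]
  if (anyDuplicated(rownames(values)) > 0) {
    values <- sum_duplicate_rows(values)
  }
  structure(
    list(
      values = values, coords = coords,
      gene_ids = rownames(values), spot_ids = colnames(values)
    ),
    class = "spatial_expression"
  )
}

#' @export
print.spatial_expression <- function(x, ...) {
  cat(sprintf(
    "<spatial_expression> %d genes x %d spots; x in [%.3g, %.3g], y in [%.3g, %.3g]\n",
    nrow(x$values), ncol(x$values),
    min(x$coords$x), max(x$coords$x), min(x$coords$y), max(x$coords$y)
  ))
  invisible(x)
}

sum_duplicate_rows <- function(m) {
  grp <- rownames(m)
  u <- unique(grp)
  if (length(u) == nrow(m)) return(m)
  agg <- Matrix::sparseMatrix(
    i = match(grp, u), j = seq_along(grp), x = 1,
    dims = c(length(u), length(grp))
  )
  out <- agg %*% m
  rownames(out) <- u
  colnames(out) <- colnames(m)
  methods::as(out, "generalMatrix")
}

#' Library-size normalization with log1p
#'
#' The default pre-transform applied before the optimal-transport distance:
#' counts are scaled so every spot (column) has the same total, multiplied by
#' the median library size, then log1p-transformed. Any negative values that
#' a custom transform may produce are clamped to zero before the expression
#' weights are normalized to probability mass.
#'
#' @param st A [spatial_expression()].
#' @return A `spatial_expression` with transformed values.
#' @export
normalize_lognorm <- function(st) {
  stopifnot(inherits(st, "spatial_expression"))
  libs <- Matrix::colSums(st$values)
  libs[libs == 0] <- 1
  scale <- stats::median(libs) / libs
  v <- st$values %*% Matrix::Diagonal(x = scale)
  v@x <- log1p(v@x)
  dimnames(v) <- dimnames(st$values)
  st$values <- methods::as(v, "generalMatrix")
  st
}

#' Apply a named or custom pre-transform to a slide
#'
#' @param st A [spatial_expression()].
#' @param transform `"lognorm"`, `"none"`, or a function mapping a
#'   `spatial_expression` to a `spatial_expression`; negative values
#'   produced by a custom transform are clamped to zero.
#' @return The transformed `spatial_expression`.
#' @export
apply_transform <- function(st, transform) {
  if (is.function(transform)) {
    out <- transform(st)
    out$values@x <- pmax(out$values@x, 0)
    return(out)
  }
  switch(match.arg(transform, c("lognorm", "none")),
    lognorm = normalize_lognorm(st),
    none = st
  )
}

#' Read a gene-by-column counts matrix
#'
#' Accepts either a MatrixMarket triplet (`.mtx` with companion feature and
#' barcode files, one name per line or first-column-of-TSV) or a dense TSV
#' whose first column holds gene names and whose header holds column names.
#' Duplicated gene symbols are collapsed by summing their rows.
#'
#' @param matrix_path Path to the `.mtx` or dense TSV file.
#' @param features_path,barcodes_path Row/column name files, required for MTX.
#' @return A sparse `dgCMatrix` with dimnames.
#' @export
read_counts <- function(matrix_path, features_path = NULL, barcodes_path = NULL) {
  if (!file.exists(matrix_path)) abort(paste0("counts file not found: ", matrix_path))
  if (grepl("\\.mtx$", matrix_path)) {
    m <- methods::as(Matrix::readMM(matrix_path), "CsparseMatrix")
    if (is.null(features_path) || is.null(barcodes_path)) {
      abort("MTX input needs features_path and barcodes_path")
    }
    feats <- read_name_column(features_path)
    cells <- read_name_column(barcodes_path)
    if (length(feats) != nrow(m) || length(cells) != ncol(m)) {
      abort(sprintf(
        "dimension mismatch: matrix is %d x %d but %d features / %d barcodes supplied",
        nrow(m), ncol(m), length(feats), length(cells)
      ))
    }
    dimnames(m) <- list(feats, cells)
  } else {
    tab <- readr::read_tsv(matrix_path, show_col_types = FALSE, progress = FALSE)
    if (nrow(tab) == 0 || ncol(tab) < 2) abort("empty counts table")
    genes <- as.character(tab[[1]])
    m <- Matrix::Matrix(as.matrix(tab[, -1]), sparse = TRUE)
    dimnames(m) <- list(genes, names(tab)[-1])
    m <- methods::as(m, "CsparseMatrix")
  }
  if (length(m@x) == 0 && prod(dim(m)) == 0) abort("empty counts matrix")
  m <- methods::as(m, "generalMatrix")
  sum_duplicate_rows(m)
}

read_name_column <- function(path) {
  x <- readr::read_tsv(path, col_names = FALSE, show_col_types = FALSE, progress = FALSE)
  as.character(x[[1]])
}

#' Write a counts matrix as MTX triplet or dense TSV
#'
#' @param m Gene-by-column matrix with dimnames.
#' @param matrix_path Output path; `.mtx` selects MatrixMarket, anything else
#'   a dense TSV with a leading `gene` column.
#' @param features_path,barcodes_path Companion name files for MTX output.
#' @return `matrix_path`, invisibly.
#' @export
write_counts <- function(m, matrix_path, features_path = NULL, barcodes_path = NULL) {
  if (grepl("\\.mtx$", matrix_path)) {
    if (is.null(features_path) || is.null(barcodes_path)) {
      abort("MTX output needs features_path and barcodes_path")
    }
    Matrix::writeMM(methods::as(Matrix::Matrix(m, sparse = TRUE), "CsparseMatrix"), matrix_path)
    writeLines(rownames(m), features_path)
    writeLines(colnames(m), barcodes_path)
  } else {
    tab <- as.data.frame(as.matrix(m))
    tab <- cbind(gene = rownames(m), tab)
    readr::write_tsv(as_tibble(tab), matrix_path)
  }
  invisible(matrix_path)
}

#' Read spot coordinates
#'
#' @param path TSV with columns `spot_id`, `x`, `y`.
#' @return A tibble.
#' @export
read_coords <- function(path) {
  tab <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  if (!all(c("spot_id", "x", "y") %in% names(tab))) {
    abort("coordinates file must have columns spot_id, x, y")
  }
  tab$spot_id <- as.character(tab$spot_id)
  as_tibble(tab)
}

#' Read a spatial slide from counts plus coordinates files
#'
#' @inheritParams read_counts
#' @param coords_path Coordinates TSV (`spot_id`, `x`, `y`).
#' @return A [spatial_expression()].
#' @export
read_spatial_expression <- function(matrix_path, coords_path,
                                    features_path = NULL, barcodes_path = NULL) {
  m <- read_counts(matrix_path, features_path, barcodes_path)
  spatial_expression(m, read_coords(coords_path))
}
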