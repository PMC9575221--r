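#' Annotate spots from deconvolution proportions
#'
#' Each spot is labeled with the cell type holding the largest proportion;
#' ties are broken by lexicographic cell-type name so the labeling is
#' deterministic.
#'
#' @param proportions Data frame with a `spot_id` column and one numeric
#'   column per cell type (non-negative fractions; rows need not sum to 1).
#' @return Tibble with columns `spot_id`, `cell_type`.
#' @examples
#' p <- data.frame(spot_id = "s1", Tcell = 0.6, Bcell = 0.4)
#' annotate_spots(p)
#' @export
annotate_spots <- function(proportions) {
  proportions <- as_tibble(proportions)
  if (!"spot_id" %in% names(proportions)) abort("proportions need a spot_id column")
  types <- setdiff(names(proportions), "spot_id")
  if (length(types) < 1) abort("proportions need at least one cell type column")
  m <- as.matrix(proportions[, types])
  if (any(m < 0, na.rm = TRUE)) abort("proportions must be non-negative")
  zero <- rowSums(m, na.rm = TRUE) == 0
  if (any(zero)) {
    abort(paste0(
      "spots with all-zero proportions cannot be annotated: ",
      paste(proportions$spot_id[zero], collapse = ", ")
    ))
  }
  ord <- order(types)
  m <- m[, ord, drop = FALSE]
  types <- types[ord]
  lab <- types[apply(m, 1, which.max)] # which.max takes the first (lexicographic) tie
  tibble(spot_id = as.character(proportions$spot_id), cell_type = lab)
}

#' Spatial distance between two cell types
#'
#' The mean, over the spots of one type, of the Euclidean distance to the
#' nearest spot of the other type; computed in both directions and averaged.
#' Symmetric in its arguments and invariant to rigid motions of the slide.
#'
#' @param coords_a,coords_b Data frames with `x`, `y` columns for the spots
#'   of each type (at least one row each).
#' @return Distance in slide units.
#' @examples
#' pair_distance(data.frame(x = c(0, 2), y = 0), data.frame(x = 0, y = 0))
#' @export
pair_distance <- function(coords_a, coords_b) {
  if (nrow(coords_a) == 0 || nrow(coords_b) == 0) {
    abort("both cell types need at least one spot")
  }
  D <- outer(seq_len(nrow(coords_a)), seq_len(nrow(coords_b)), function(i, j) {
    sqrt((coords_a$x[i] - coords_b$x[j])^2 + (coords_a$y[i] - coords_b$y[j])^2)
  })
  (mean(apply(D, 1, min)) + mean(apply(D, 2, min))) / 2
}

#' Distances between all cell-type pairs on a slide
#'
#' @param annotation Tibble with `spot_id`, `cell_type` (see
#'   [annotate_spots()]).
#' @param coords Tibble with `spot_id`, `x`, `y`.
#' @return Tibble of class `cci_pairs` with one row per unordered pair:
#'   `type_a`, `type_b` (alphabetical), `distance`.
#' @export
celltype_pair_distances <- function(annotation, coords) {
  dat <- inner_join(as_tibble(annotation), as_tibble(coords), by = "spot_id")
  if (nrow(dat) == 0) abort("annotation and coordinates share no spot_ids")
  types <- sort(unique(dat$cell_type))
  if (length(types) < 2) abort("need at least two cell types")
  combos <- utils::combn(types, 2)
  rows <- purrr::map_dfr(seq_len(ncol(combos)), function(k) {
    a <- combos[1, k]
    b <- combos[2, k]
    tibble(
      type_a = a, type_b = b,
      distance = pair_distance(
        dat[dat$cell_type == a, c("x", "y")],
        dat[dat$cell_type == b, c("x", "y")]
      )
    )
  })
  structure(rows, class = c("cci_pairs", class(rows)))
}

#' Classify cell-type pairs into near, medium and far
#'
#' One-dimensional k-means (k = 3) on the pair distances; the three clusters
#' are labeled near/medium/far in ascending order of their mean distance.
#' For up to 50 pairs the exact dynamic-programming optimum is used (1-D
#' k-means is solvable exactly), above that `stats::kmeans` with multiple
#' restarts under the given seed. With fewer than three distinct distances a
#' tertile split is used instead, with a warning; if every pair is
#' equidistant all pairs are labeled `medium`.
#'
#' @param pairs A `cci_pairs` tibble from [celltype_pair_distances()].
#' @param seed Integer seed for the restarted k-means path.
#' @return The input with a `pair_class` column (`near`/`medium`/`far`).
#' @export
classify_pairs <- function(pairs, seed = 1L) {
  d <- pairs$distance
  n <- length(d)
  if (n == 0) {
    pairs$pair_class <- character()
    return(pairs)
  }
  if (length(unique(d)) < 3) {
    if (length(unique(d)) == 1) {
      warn("all cell-type pairs are equidistant; labeling everything medium")
      pairs$pair_class <- rep("medium", n)
      return(pairs)
    }
    warn("fewer than 3 distinct distances; falling back to a range-tertile split")
    z <- (d - min(d)) / (max(d) - min(d))
    pairs$pair_class <- ifelse(z < 1 / 3, "near", ifelse(z <= 2 / 3, "medium", "far"))
    return(pairs)
  }
  if (n <= 50) {
    cl <- kmeans1d_exact(d, 3)
  } else {
    set.seed(seed)
    cl <- kmeans(d, centers = 3, nstart = 25)$cluster
  }
  mu <- tapply(d, cl, mean)
  lab <- setNames(c("near", "medium", "far")[rank(mu)], names(mu))
  pairs$pair_class <- unname(lab[as.character(cl)])
  pairs
}

# exact 1-D k-means by dynamic programming on the sorted values
# (minimizes within-cluster sum of squares; clusters are contiguous in 1-D)
kmeans1d_exact <- function(x, k) {
  n <- length(x)
  ord <- order(x)
  xs <- x[ord]
  cs <- cumsum(xs)
  cs2 <- cumsum(xs^2)
  ss <- function(i, j) {
    # within-SS of xs[i..j]
    s <- cs[j] - if (i > 1) cs[i - 1] else 0
    s2 <- cs2[j] - if (i > 1) cs2[i - 1] else 0
    s2 - s^2 / (j - i + 1)
  }
  D <- matrix(Inf, k, n)
  B <- matrix(0L, k, n)
  for (j in 1:n) {
    D[1, j] <- ss(1, j)
    B[1, j] <- 1L
  }
  for (q in 2:k) {
    for (j in q:n) {
      for (i in q:j) {
        v <- D[q - 1, i - 1] + ss(i, j)
        if (v < D[q, j]) {
          D[q, j] <- v
          B[q, j] <- i
        }
      }
    }
  }
  cl_sorted <- integer(n)
  j <- n
  for (q in k:1) {
    i <- B[q, j]
    cl_sorted[i:j] <- q
    j <- i - 1
  }
  cl <- integer(n)
  cl[ord] <- cl_sorted
  cl
}

#' Write / read a cell-type pair table
#'
#' @param pairs A `cci_pairs` tibble.
#' @param path TSV path.
#' @export
write_pairs <- function(pairs, path) {
  readr::write_tsv(as_tibble(pairs), path)
  invisible(path)
}

#' @rdname write_pairs
#' @export
read_pairs <- function(path) {
  out <- as_tibble(readr::read_tsv(path, show_col_types = FALSE, progress = FALSE))
  structure(out, class = c("cci_pairs", class(out)))
}
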