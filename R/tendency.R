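#' Permutation null for the ligand-receptor spatial distance
#'
#' For each replicate, the ligand's and the receptor's per-spot expression
#' values are independently reassigned to coordinates drawn by permuting the
#' full set of slide spot positions; the two permuted distributions are then
#' rebuilt and their symmetrized Sinkhorn distance recorded. Permuting over
#' all slide spots (not only the expressed subset) is the most literal
#' reading of shuffling spot positions on the slide.
#'
#' @param st A [spatial_expression()] (normalized upstream).
#' @param ligand,receptor Character vectors of gene symbols (complexes allowed).
#' @param n_perm Number of permutation replicates, default 1000.
#' @param reg Sinkhorn regularization, default 0.001.
#' @param seed Optional integer seed for reproducibility.
#' @return Numeric vector of `n_perm` null distances.
#' @export
permutation_null <- function(st, ligand, receptor, n_perm = 1000, reg = 0.001,
                             seed = NULL) {
  if (n_perm < 1) abort("n_perm must be at least 1")
  if (!is.null(seed)) set.seed(seed)
  L <- gene_values(st, ligand)
  R <- gene_values(st, receptor)
  li <- which(L > 0)
  ri <- which(R > 0)
  lw <- L[li] / sum(L[li])
  rw <- R[ri] / sum(R[ri])
  xs <- st$coords$x
  ys <- st$coords$y
  n <- length(xs)
  vapply(seq_len(n_perm), function(k) {
    pl <- sample.int(n)
    pr <- sample.int(n)
    .wasserstein_points_cpp(
      xs[pl[li]], ys[pl[li]], lw,
      xs[pr[ri]], ys[pr[ri]], rw, reg = reg
    )
  }, numeric(1))
}

gene_values <- function(st, genes) {
  miss <- setdiff(genes, st$gene_ids)
  if (length(miss) > 0) {
    abort(paste0("gene(s) absent from slide: ", paste(miss, collapse = ", ")))
  }
  sub <- as.matrix(st$values[genes, , drop = FALSE])
  v <- if (length(genes) == 1) as.numeric(sub) else unname(apply(sub, 2, min))
  v <- pmax(v, 0)
  if (sum(v) <= 0) {
    abort(paste0(
      "degenerate distribution: no spot expresses ",
      paste(genes, collapse = "+")
    ))
  }
  v
}

#' Summary statistics of a permutation test
#'
#' `d_ratio` is the observed distance divided by the mean null distance
#' (below one: ligand and receptor are closer than expected; above one:
#' farther). One-sided P-values use the add-one (permutation-inclusive)
#' estimator, which guarantees values in (0, 1].
#'
#' @param d_real Observed distance.
#' @param d_sims Numeric vector of null distances.
#' @return A one-row tibble with `d_sim_mean`, `d_ratio`, `p_left`,
#'   `p_right`, `n_perm`.
#' @export
tendency_statistics <- function(d_real, d_sims) {
  if (length(d_sims) == 0) abort("empty permutation null")
  mu <- mean(d_sims)
  if (mu <= 0) abort("degenerate null: mean permuted distance is zero")
  n <- length(d_sims)
  tibble(
    d_sim_mean = mu,
    d_ratio = d_real / mu,
    p_left = (sum(d_sims <= d_real) + 1) / (n + 1),
    p_right = (sum(d_sims >= d_real) + 1) / (n + 1),
    n_perm = n
  )
}

#' Spatial interaction tendency of ligand-receptor pairs
#'
#' For each database interaction, computes the symmetrized Sinkhorn distance
#' between the ligand and receptor spatial expression distributions, a
#' permutation null over spot positions, the distance ratio and one-sided
#' P-values. The slide is normalized with `transform` before any distance is
#' measured.
#'
#' @param st A [spatial_expression()] with raw counts.
#' @param db An `lr_database` (run [filter_by_coverage()] first, or let this
#'   function apply it via `min_spot_fraction`).
#' @param n_perm Permutation replicates per interaction, default 1000.
#' @param reg Sinkhorn regularization, default 0.001.
#' @param min_spot_fraction Coverage filter applied before scoring,
#'   default 0.10.
#' @param transform `"lognorm"` (library-size scaling then log1p, the
#'   default), `"none"`, or a function `spatial_expression -> spatial_expression`.
#' @param seed Optional integer seed; permutations are drawn in database
#'   order, so the full table is reproducible.
#' @return A tibble of class `cci_tendency` with one row per interaction:
#'   `interaction_name`, `ligand`, `receptor`, `annotation`, `d_real`,
#'   `d_sim_mean`, `d_ratio`, `p_left`, `p_right`, `n_perm`.
#' @export
lr_spatial_tendency <- function(st, db, n_perm = 1000, reg = 0.001,
                                min_spot_fraction = 0.10,
                                transform = "lognorm", seed = NULL) {
  stopifnot(inherits(st, "spatial_expression"), inherits(db, "lr_database"))
  db <- filter_by_coverage(db, st, min_spot_fraction)
  if (nrow(db) == 0) {
    warn("no interaction passes the coverage filter")
    return(empty_tendency())
  }
  stn <- apply_transform(st, transform)
  if (!is.null(seed)) set.seed(seed)
  rows <- purrr::pmap_dfr(
    list(db$interaction_name, db$ligand, db$receptor, db$annotation,
         db$ligand_subunits, db$receptor_subunits),
    function(nm, lig, rec, ann, ls, rs) {
      L <- gene_distribution(stn, ls)
      R <- gene_distribution(stn, rs)
      d_real <- wasserstein_lr(L, R, reg = reg)
      sims <- permutation_null(stn, ls, rs, n_perm = n_perm, reg = reg)
      stats <- tendency_statistics(d_real, sims)
      dplyr::bind_cols(
        tibble(interaction_name = nm, ligand = lig, receptor = rec,
               annotation = ann, d_real = d_real),
        stats
      )
    }
  )
  structure(rows, class = c("cci_tendency", class(rows)))
}

empty_tendency <- function() {
  out <- tibble(
    interaction_name = character(), ligand = character(),
    receptor = character(), annotation = character(),
    d_real = numeric(), d_sim_mean = numeric(), d_ratio = numeric(),
    p_left = numeric(), p_right = numeric(), n_perm = integer(),
    range_class = character()
  )
  structure(out, class = c("cci_tendency", class(out)))
}

#' Classify interactions into short-, medium- and long-range
#'
#' Short-range candidates are the intersection of the smallest
#' `top_fraction` of interactions by `d_ratio` and by left-sided P-value;
#' long-range candidates mirror this with the largest `d_ratio` and the
#' right-sided P-value. Candidates whose relevant one-sided P-value falls
#' below `alpha` become `short`/`long`; everything else is `medium`.
#' `strategy = "composite"` instead ranks by the sum of the two ranks.
#' Ties at the cutoff boundary are broken by P-value, then by interaction
#' name, so the classification is deterministic.
#'
#' @param tendency A `cci_tendency` tibble from [lr_spatial_tendency()].
#' @param top_fraction Fraction of ranked interactions kept as candidates on
#'   each side, default 0.10 (0.15 is a useful relaxation for low-coverage
#'   slides).
#' @param alpha One-sided significance threshold, default 0.01.
#' @param strategy `"intersection"` (default) or `"composite"`.
#' @return The input with a `range_class` column (`short`/`medium`/`long`).
#' @export
classify_ranges <- function(tendency, top_fraction = 0.10, alpha = 0.01,
                            strategy = c("intersection", "composite")) {
  strategy <- match.arg(strategy)
  n <- nrow(tendency)
  if (n == 0) {
    tendency$range_class <- character()
    return(tendency)
  }
  k <- floor(top_fraction * n)
  short_idx <- candidate_set(
    tendency$d_ratio, tendency$p_left, tendency$interaction_name, k, strategy
  )
  long_idx <- candidate_set(
    -tendency$d_ratio, tendency$p_right, tendency$interaction_name, k, strategy
  )
  short_idx <- short_idx[tendency$p_left[short_idx] < alpha]
  long_idx <- long_idx[tendency$p_right[long_idx] < alpha]
  both <- intersect(short_idx, long_idx)
  if (length(both) > 0) {
    # a pair cannot be both; keep the side with the smaller one-sided P
    drop_long <- both[tendency$p_left[both] <= tendency$p_right[both]]
    long_idx <- setdiff(long_idx, drop_long)
    short_idx <- setdiff(short_idx, setdiff(both, drop_long))
  }
  cls <- rep("medium", n)
  cls[short_idx] <- "short"
  cls[long_idx] <- "long"
  tendency$range_class <- cls
  tendency
}

candidate_set <- function(stat, p, name, k, strategy) {
  if (k < 1) return(integer(0))
  ord_stat <- order(stat, p, name)
  ord_p <- order(p, stat, name)
  if (strategy == "intersection") {
    intersect(ord_stat[seq_len(k)], ord_p[seq_len(k)])
  } else {
    r <- rank(stat, ties.method = "min") + rank(p, ties.method = "min")
    order(r, p, name)[seq_len(k)]
  }
}

#' Write / read a tendency table
#'
#' @param tendency A `cci_tendency` tibble (with or without `range_class`).
#' @param path TSV path.
#' @return `path` (write) or the tibble (read).
#' @export
write_tendency <- function(tendency, path) {
  readr::write_tsv(as_tibble(tendency), path)
  invisible(path)
}

#' @rdname write_tendency
#' @export
read_tendency <- function(path) {
  out <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  structure(as_tibble(out), class = c("cci_tendency", class(as_tibble(out))))
}
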