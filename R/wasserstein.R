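#' Spatial expression distribution of a gene or complex
#'
#' Turns per-spot expression of a single gene, or the per-spot elementwise
#' minimum over the subunits of a complex, into a discrete probability
#' distribution over spot coordinates. A complex needs all of its subunits,
#' hence the minimum. Zero-weight spots are dropped and weights are
#' normalized to total mass one.
#'
#' @param st A [spatial_expression()] (typically already normalized).
#' @param genes Character vector of gene symbols (length one for a single
#'   gene, more for a complex).
#' @return Tibble with columns `spot_id`, `x`, `y`, `weight` (weights sum
#'   to 1).
#' @export
gene_distribution <- function(st, genes) {
  stopifnot(inherits(st, "spatial_expression"))
  miss <- setdiff(genes, st$gene_ids)
  if (length(miss) > 0) {
    abort(paste0("gene(s) absent from slide: ", paste(miss, collapse = ", ")))
  }
  sub <- as.matrix(st$values[genes, , drop = FALSE])
  v <- if (length(genes) == 1) as.numeric(sub) else unname(apply(sub, 2, min))
  v <- pmax(v, 0)
  tot <- sum(v)
  if (tot <= 0) {
    abort(paste0(
      "degenerate distribution: no spot expresses ",
      paste(genes, collapse = "+")
    ))
  }
  keep <- v > 0
  tibble(
    spot_id = st$spot_ids[keep],
    x = st$coords$x[keep], y = st$coords$y[keep],
    weight = v[keep] / tot
  )
}

#' Symmetrized entropic-regularized Wasserstein distance
#'
#' Computes the entropic-regularized optimal-transport cost between two
#' weighted point sets under the Euclidean ground metric, in both transport
#' directions, and returns their mean. The two directions can differ
#' slightly at finite regularization; averaging makes the statistic exactly
#' symmetric in its arguments.
#'
#' @param L,R Weighted point sets as returned by [gene_distribution()]
#'   (columns `x`, `y`, `weight`).
#' @param reg Entropic regularization strength in slide-distance units,
#'   default 0.001.
#' @param max_iter,tol Solver controls for the final annealing stage.
#' @return Distance in slide units (non-negative scalar).
#' @export
wasserstein_lr <- function(L, R, reg = 0.001, max_iter = 150, tol = 1e-4) {
  check_point_set(L, "L")
  check_point_set(R, "R")
  .wasserstein_points_cpp(
    L$x, L$y, L$weight, R$x, R$y, R$weight,
    reg = reg, max_iter = max_iter, tol = tol
  )
}

check_point_set <- function(p, label) {
  if (!all(c("x", "y", "weight") %in% names(p)) || nrow(p) == 0) {
    abort(paste0(label, " must be a non-empty point set with x, y, weight"))
  }
  if (abs(sum(p$weight) - 1) > 1e-9) {
    abort(paste0(label, " weights must sum to 1 (tolerance 1e-9)"))
  }
  invisible(p)
}

#' Exact earth mover's distance (linear-program oracle)
#'
#' Solves the unregularized optimal-transport problem exactly with a simplex
#' linear program. Intended as an independent reference for small instances
#' (total point count up to a few hundred); the Sinkhorn solver is the
#' production path.
#'
#' @inheritParams wasserstein_lr
#' @return Exact transport cost in slide units.
#' @export
exact_emd <- function(L, R) {
  check_point_set(L, "L")
  check_point_set(R, "R")
  if (nrow(L) + nrow(R) > 400) {
    abort("exact_emd is an oracle for small instances (<= ~400 points total)")
  }
  a <- L$weight / sum(L$weight)
  b <- R$weight / sum(R$weight)
  C <- outer(seq_len(nrow(L)), seq_len(nrow(R)), function(i, j) {
    sqrt((L$x[i] - R$x[j])^2 + (L$y[i] - R$y[j])^2)
  })
  m <- length(a)
  n <- length(b)
  if (m == 1 && n == 1) return(C[1, 1])
  Aeq <- matrix(0, m + n, m * n)
  for (i in seq_len(m)) Aeq[i, (seq_len(n) - 1) * m + i] <- 1
  for (j in seq_len(n)) Aeq[m + j, (j - 1) * m + seq_len(m)] <- 1
  # one marginal constraint is redundant; dropping it keeps the LP full rank
  sol <- pracma::linprog(
    as.vector(C),
    Aeq = Aeq[-(m + n), , drop = FALSE], beq = c(a, b)[-(m + n)],
    maxiter = 20000
  )
  if (is.null(sol$fval) || !is.finite(sol$fval)) {
    abort("exact_emd: linear program failed (infeasible marginals?)")
  }
  sol$fval
}
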