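#' Expected ranked interaction lists
#'
#' Builds the expected short-range list (all `short` interactions sorted by
#' ascending `d_ratio`, then ascending left-sided P, then name) and the
#' expected long-range list (all `long` interactions sorted by descending
#' `d_ratio`, then ascending right-sided P, then name). The P-value carried
#' into each entry is the relevant one-sided permutation P.
#'
#' @param tendency A classified `cci_tendency` (see [classify_ranges()]).
#' @return A list with tibbles `short` and `long`, each with columns
#'   `interaction_name`, `ligand`, `receptor`, `key`, `p_value`. A side with
#'   no interactions yields an empty tibble with a warning; DES for that
#'   side is undefined and skipped downstream.
#' @export
build_expected_lists <- function(tendency) {
  if (!"range_class" %in% names(tendency)) {
    abort("run classify_ranges() before building expected lists")
  }
  mk <- function(cls, pcol, desc_d) {
    sub <- tendency[tendency$range_class == cls, , drop = FALSE]
    if (nrow(sub) == 0) {
      warn(paste0("no ", cls, "-range interactions; that DES side will be skipped"))
      return(tibble(
        interaction_name = character(), ligand = character(),
        receptor = character(), key = character(), p_value = numeric()
      ))
    }
    o <- order(if (desc_d) -sub$d_ratio else sub$d_ratio,
               sub[[pcol]], sub$interaction_name)
    sub <- sub[o, , drop = FALSE]
    tibble(
      interaction_name = sub$interaction_name,
      ligand = sub$ligand, receptor = sub$receptor,
      key = lr_key(sub$ligand, sub$receptor),
      p_value = sub[[pcol]]
    )
  }
  list(
    short = mk("short", "p_left", desc_d = FALSE),
    long = mk("long", "p_right", desc_d = TRUE)
  )
}

# canonical ligand->receptor key; subunit order within a complex is ignored
lr_key <- function(ligand, receptor) {
  canon <- function(x) {
    vapply(strsplit(as.character(x), "+", fixed = TRUE), function(s) {
      paste(sort(trimws(s)), collapse = "+")
    }, character(1))
  }
  paste(canon(ligand), canon(receptor), sep = "->")
}

#' Distance enrichment score for one cell-type pair
#'
#' A GSEA-style running-sum statistic. Walking down the expected ranked list
#' `L`, a matched interaction (present in the predicted set `S`) adds its
#' normalized confidence weight `(1 - p) / sum(1 - p over matches)`; an
#' unmatched one subtracts `1 / (ns - nm)` where `ns = |L|` and `nm` is the
#' number of matches. The DES is the maximum of the running sum. Edge cases:
#' no matches gives 0 (no matched mass); all matched gives 1 (no unmatched
#' penalty exists).
#'
#' @param S Character vector of predicted interaction keys (see the `key`
#'   column of [build_expected_lists()] output), treated as a set.
#' @param L One expected ranked list tibble (`key`, `p_value`).
#' @return DES in \[0, 1\].
#' @export
des_for_pair <- function(S, L) {
  ns <- nrow(L)
  if (ns == 0) abort("expected list is empty")
  hit <- L$key %in% unique(S)
  nm <- sum(hit)
  if (nm == 0) return(0)
  if (nm == ns) return(1)
  w <- 1 - L$p_value
  tot <- sum(w[hit])
  inc <- if (tot > 0) {
    ifelse(hit, w / tot, -1 / (ns - nm))
  } else {
    # all matched P-values equal 1: fall back to uniform matched weight
    ifelse(hit, 1 / nm, -1 / (ns - nm))
  }
  # the running maximum is >= 0 whenever a match exists; clamp float noise
  max(0, max(cumsum(inc)))
}

#' Score one tool's predictions with the distance enrichment score
#'
#' For every near cell-type pair the tool's predictions between the two
#' types (both directions pooled, since the pair distance is symmetric) are
#' scored against the expected short-range list; far pairs are scored
#' against the long-range list; medium pairs are skipped. The mean DES is
#' the unweighted mean over all scored pairs.
#'
#' @param pred A prediction table: tibble with columns `tool`,
#'   `source_celltype`, `target_celltype`, `ligand`, `receptor` (and
#'   optionally `score`, `pvalue`).
#' @param pairs A classified `cci_pairs` (see [classify_pairs()]).
#' @param lists Expected lists from [build_expected_lists()].
#' @return A tibble of class `cci_des` with one row per scored pair
#'   (`tool`, `type_a`, `type_b`, `pair_class`, `n_pred`, `n_match`, `des`)
#'   and attributes `tool` and `mean_des`.
#' @export
tool_des <- function(pred, pairs, lists) {
  pred <- as_tibble(pred)
  check_prediction_table(pred)
  tool <- if (nrow(pred) > 0) pred$tool[1] else "unknown"
  if (nrow(pred) == 0) warn("empty prediction table: DES is 0 for every pair")
  sided <- list(near = lists$short, far = lists$long)
  use <- pairs[pairs$pair_class %in% c("near", "far"), , drop = FALSE]
  if (nrow(use) == 0) abort("no near or far cell-type pairs to score")
  pkey <- lr_key(pred$ligand, pred$receptor)
  rows <- purrr::pmap_dfr(
    list(use$type_a, use$type_b, use$pair_class),
    function(a, b, cls) {
      L <- sided[[cls]]
      if (nrow(L) == 0) return(NULL) # side undefined, skip
      sel <- (pred$source_celltype == a & pred$target_celltype == b) |
        (pred$source_celltype == b & pred$target_celltype == a)
      S <- unique(pkey[sel])
      tibble(
        tool = tool, type_a = a, type_b = b, pair_class = cls,
        n_pred = sum(sel), n_match = sum(L$key %in% S),
        des = des_for_pair(S, L)
      )
    }
  )
  if (nrow(rows) == 0) abort("no scorable pair: both expected lists are empty")
  structure(rows,
    class = c("cci_des", class(rows)),
    tool = tool, mean_des = mean(rows$des)
  )
}

check_prediction_table <- function(pred) {
  need <- c("tool", "source_celltype", "target_celltype", "ligand", "receptor")
  miss <- setdiff(need, names(pred))
  if (length(miss) > 0) {
    abort(paste0("prediction table is missing column(s): ", paste(miss, collapse = ", ")))
  }
  invisible(pred)
}

#' Rank tools by mean DES
#'
#' Rank 1 is the largest mean DES; ties share the mean of the tied rank
#' positions, and an average rank across datasets is the mean of the
#' per-dataset ranks.
#'
#' @param des_results A list of `cci_des` objects (one per tool), or a
#'   tibble with columns `tool` and `mean_des`.
#' @return Tibble with `tool`, `mean_des`, `rank`, sorted by rank.
#' @export
rank_tools <- function(des_results) {
  if (inherits(des_results, "data.frame")) {
    tab <- as_tibble(des_results)[, c("tool", "mean_des")]
  } else {
    tab <- purrr::map_dfr(des_results, function(r) {
      tibble(tool = attr(r, "tool"), mean_des = attr(r, "mean_des"))
    })
  }
  if (nrow(tab) == 0) abort("no DES results to rank")
  tab$rank <- rank(-tab$mean_des, ties.method = "average")
  arrange(tab, .data$rank, .data$tool)
}
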