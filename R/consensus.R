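#' Consensus of commonly identified interactions
#'
#' Pools several tools' prediction tables and keeps, per directed cell-type
#' pair, every interaction reported by at least `min_tools` distinct tools.
#' The consensus serves as a relative reference set: it reflects agreement
#' between tools, not ground truth.
#'
#' @param tables A list of prediction tables (tibbles with `tool`,
#'   `source_celltype`, `target_celltype`, `ligand`, `receptor`), or one
#'   tibble pooling them.
#' @param min_tools Minimum number of distinct tools, default 3.
#' @return Tibble of class `cci_consensus` with columns `source_celltype`,
#'   `target_celltype`, `ligand`, `receptor`, `n_tools`; attribute
#'   `contributing_tools`.
#' @export
build_consensus <- function(tables, min_tools = 3) {
  pool <- if (inherits(tables, "data.frame")) as_tibble(tables) else bind_rows(tables)
  check_prediction_table(pool)
  tools <- unique(pool$tool)
  if (length(tools) < min_tools) {
    abort(sprintf(
      "consensus needs at least min_tools = %d tables, got %d", min_tools, length(tools)
    ))
  }
  pool$key <- lr_key(pool$ligand, pool$receptor)
  out <- pool |>
    distinct(.data$tool, .data$source_celltype, .data$target_celltype,
             .data$key, .keep_all = TRUE) |>
    group_by(.data$source_celltype, .data$target_celltype, .data$key) |>
    summarise(
      ligand = .data$ligand[1], receptor = .data$receptor[1],
      n_tools = dplyr::n_distinct(.data$tool), .groups = "drop"
    ) |>
    filter(.data$n_tools >= min_tools) |>
    select("source_celltype", "target_celltype", "ligand", "receptor", "n_tools") |>
    arrange(.data$source_celltype, .data$target_celltype, .data$ligand, .data$receptor)
  structure(out, class = c("cci_consensus", class(out)), contributing_tools = tools)
}

#' Precision, recall and F1 against a reference set
#'
#' Counts true/false positives and false negatives per directed cell-type
#' pair against the reference (a consensus set or a simulated ground-truth
#' table), computes precision/recall/F1 per pair, macro-averages over pairs
#' with a non-empty reference (the primary report), and also pools the raw
#' counts into micro-averaged metrics.
#'
#' @param pred A prediction table for one tool.
#' @param reference A `cci_consensus`, or any tibble with
#'   `source_celltype`, `target_celltype`, `ligand`, `receptor`.
#' @return One-row tibble of class `cci_accuracy`: `tool`, macro
#'   `precision`, `recall`, `f1`, pooled counts `tp`, `fp`, `fn`, and
#'   `micro_precision`, `micro_recall`, `micro_f1`. The per-pair table is
#'   attached as attribute `per_pair`.
#' @export
accuracy_vs_reference <- function(pred, reference) {
  pred <- as_tibble(pred)
  check_prediction_table(pred)
  ref <- as_tibble(reference)
  if (nrow(ref) == 0) abort("reference set is empty")
  tool <- if (nrow(pred) > 0) pred$tool[1] else "unknown"
  ref$key <- lr_key(ref$ligand, ref$receptor)
  pred$key <- if (nrow(pred) > 0) lr_key(pred$ligand, pred$receptor) else character(0)
  ref_sets <- split(ref$key, paste(ref$source_celltype, ref$target_celltype, sep = "\r"))
  per_pair <- purrr::imap_dfr(ref_sets, function(rk, pair) {
    ct <- strsplit(pair, "\r", fixed = TRUE)[[1]]
    pk <- unique(pred$key[pred$source_celltype == ct[1] & pred$target_celltype == ct[2]])
    rk <- unique(rk)
    tp <- length(intersect(pk, rk))
    fp <- length(setdiff(pk, rk))
    fn <- length(setdiff(rk, pk))
    p <- if (tp + fp > 0) tp / (tp + fp) else 0
    r <- if (tp + fn > 0) tp / (tp + fn) else 0
    tibble(
      source_celltype = ct[1], target_celltype = ct[2],
      tp = tp, fp = fp, fn = fn,
      precision = p, recall = r, f1 = if (p + r > 0) 2 * p * r / (p + r) else 0
    )
  })
  tp <- sum(per_pair$tp)
  fp <- sum(per_pair$fp)
  fn <- sum(per_pair$fn)
  mp <- if (tp + fp > 0) tp / (tp + fp) else 0
  mr <- if (tp + fn > 0) tp / (tp + fn) else 0
  out <- tibble(
    tool = tool,
    precision = mean(per_pair$precision),
    recall = mean(per_pair$recall),
    f1 = mean(per_pair$f1),
    tp = tp, fp = fp, fn = fn,
    micro_precision = mp, micro_recall = mr,
    micro_f1 = if (mp + mr > 0) 2 * mp * mr / (mp + mr) else 0
  )
  structure(out, class = c("cci_accuracy", class(out)), per_pair = per_pair)
}

#' Expression-product baseline predictor
#'
#' A deliberately simple reference predictor: for every ordered
#' (sender, receiver) cell-type pair, each database interaction is scored by
#' the mean ligand expression in the sender times the mean receptor
#' expression in the receiver (complexes take the minimum subunit mean on
#' each side), and the `top_n` positive-score interactions per direction are
#' emitted.
#'
#' @param sc_counts Gene-by-cell counts matrix with dimnames.
#' @param cell_annotation Tibble with `cell_id`, `cell_type`.
#' @param db An `lr_database`.
#' @param top_n Interactions kept per direction, default 10.
#' @param tool Name recorded in the output, default `"LR_product"`.
#' @return A prediction table (may be empty if nothing scores above zero).
#' @export
lr_product_baseline <- function(sc_counts, cell_annotation, db, top_n = 10,
                                tool = "LR_product") {
  ann <- as_tibble(cell_annotation)
  if (!all(c("cell_id", "cell_type") %in% names(ann))) {
    abort("cell annotation needs cell_id and cell_type columns")
  }
  types <- sort(unique(ann$cell_type))
  if (length(types) < 2) abort("need at least two cell types")
  means <- sapply(types, function(ct) {
    cells <- ann$cell_id[ann$cell_type == ct]
    Matrix::rowMeans(sc_counts[, colnames(sc_counts) %in% cells, drop = FALSE])
  })
  side_mean <- function(subunits, ct) {
    if (!all(subunits %in% rownames(means))) return(0)
    min(means[subunits, ct])
  }
  grid <- expand.grid(sender = types, receiver = types, stringsAsFactors = FALSE)
  grid <- grid[grid$sender != grid$receiver, ]
  out <- purrr::pmap_dfr(grid, function(sender, receiver) {
    sc <- purrr::map2_dbl(
      db$ligand_subunits, db$receptor_subunits,
      ~ side_mean(.x, sender) * side_mean(.y, receiver)
    )
    keep <- which(sc > 0)
    if (length(keep) == 0) return(NULL)
    keep <- keep[order(-sc[keep], db$interaction_name[keep])]
    keep <- head(keep, top_n)
    tibble(
      tool = tool, source_celltype = sender, target_celltype = receiver,
      ligand = db$ligand[keep], receptor = db$receptor[keep],
      score = sc[keep], pvalue = NA_real_
    )
  })
  if (is.null(out) || nrow(out) == 0) {
    out <- tibble(
      tool = character(), source_celltype = character(),
      target_celltype = character(), ligand = character(),
      receptor = character(), score = numeric(), pvalue = numeric()
    )
  }
  out
}

#' Read / write prediction tables
#'
#' Prediction tables are TSV files with columns `tool`, `source_celltype`,
#' `target_celltype`, `ligand`, `receptor`, `score`, `pvalue` (`pvalue` may
#' be NA).
#'
#' @param path TSV path.
#' @return A tibble.
#' @export
read_predictions <- function(path) {
  out <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  check_prediction_table(out)
  # all-NA pvalue/score columns must stay numeric
  for (col in intersect(c("score", "pvalue"), names(out))) {
    out[[col]] <- as.numeric(out[[col]])
  }
  as_tibble(out)
}

#' @rdname read_predictions
#' @param pred The prediction table to write.
#' @export
write_predictions <- function(pred, path) {
  check_prediction_table(pred)
  readr::write_tsv(as_tibble(pred), path)
  invisible(path)
}
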