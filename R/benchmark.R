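#' Benchmark configuration
#'
#' Numeric parameters of the full evaluation pipeline, with the defaults
#' used on real slides: 1000 permutations, Sinkhorn reg 0.001, top 10%
#' candidate fraction, one-sided alpha 0.01, consensus threshold of 3
#' tools, 10 baseline interactions per direction.
#'
#' @param n_perm,reg,top_fraction,alpha,min_spot_fraction Spatial-tendency
#'   parameters (see [lr_spatial_tendency()] and [classify_ranges()]).
#' @param min_tools Consensus threshold (see [build_consensus()]).
#' @param top_n_baseline Baseline predictions per direction.
#' @param seed Integer seed for every stochastic stage.
#' @return A list of class `benchmark_config`.
#' @export
benchmark_config <- function(n_perm = 1000, reg = 0.001, top_fraction = 0.10,
                             alpha = 0.01, min_spot_fraction = 0.10,
                             min_tools = 3, top_n_baseline = 10, seed = 1L) {
  stopifnot(
    top_fraction > 0, top_fraction < 1, alpha > 0, alpha < 1,
    min_spot_fraction > 0, min_spot_fraction < 1,
    n_perm >= 1, min_tools >= 1, top_n_baseline >= 1
  )
  structure(
    list(
      n_perm = n_perm, reg = reg, top_fraction = top_fraction, alpha = alpha,
      min_spot_fraction = min_spot_fraction, min_tools = min_tools,
      top_n_baseline = top_n_baseline, seed = as.integer(seed)
    ),
    class = "benchmark_config"
  )
}

#' Run the full evaluation pipeline
#'
#' Executes, in order: multi-subunit expansion and coverage filtering of the
#' database, spatial-tendency scoring and short/long-range classification,
#' spot annotation (when proportions are given) and near/far cell-type pair
#' classification, expected ranked lists, per-tool DES, tool ranking, the
#' consensus reference and per-tool precision/recall/F1. All tables are
#' written to `out_dir` when given, together with a JSON summary and a run
#' log carrying the seed and parameters.
#'
#' @param st A [spatial_expression()] with raw counts.
#' @param db An `lr_database`.
#' @param predictions Named list of prediction tables (one per tool).
#' @param annotation Spot annotation tibble (`spot_id`, `cell_type`), or
#'   `NULL` when `proportions` is given.
#' @param proportions Spot-by-type proportions (see [annotate_spots()]).
#' @param config A [benchmark_config()].
#' @param sc_counts,cell_annotation Optional matched scRNA-seq data; when
#'   given, the expression-product baseline is added to the tool set.
#' @param out_dir Optional output directory.
#' @return A list of class `cci_benchmark`: `tendency`, `pairs`, `lists`,
#'   `des` (list of per-tool `cci_des`), `ranking`, `consensus`,
#'   `accuracy`, `config`.
#' @export
run_benchmark <- function(st, db, predictions, annotation = NULL,
                          proportions = NULL, config = benchmark_config(),
                          sc_counts = NULL, cell_annotation = NULL,
                          out_dir = NULL) {
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      abort(paste0("benchmark stage '", name, "' failed: ", conditionMessage(e)))
    })
  }
  if (is.null(annotation) && is.null(proportions)) {
    abort("supply either a spot annotation or a proportions table")
  }
  if (is.null(names(predictions)) || any(!nzchar(names(predictions)))) {
    names(predictions) <- purrr::map_chr(predictions, ~ .x$tool[1])
  }

  db <- stage("database", expand_multisubunit(db))
  tend <- stage("tendency", lr_spatial_tendency(
    st, db,
    n_perm = config$n_perm, reg = config$reg,
    min_spot_fraction = config$min_spot_fraction, seed = config$seed
  ))
  tend <- stage("classification", classify_ranges(
    tend,
    top_fraction = config$top_fraction, alpha = config$alpha
  ))
  if (is.null(annotation)) annotation <- stage("annotation", annotate_spots(proportions))
  pairs <- stage("pairs", classify_pairs(
    celltype_pair_distances(annotation, st$coords),
    seed = config$seed
  ))
  lists <- stage("expected-lists", build_expected_lists(tend))

  if (!is.null(sc_counts) && !is.null(cell_annotation)) {
    base <- stage("baseline", lr_product_baseline(
      sc_counts, cell_annotation, db,
      top_n = config$top_n_baseline
    ))
    if (nrow(base) > 0) predictions$LR_product <- base
  }

  des <- stage("des", purrr::map(predictions, tool_des, pairs = pairs, lists = lists))
  ranking <- stage("ranking", rank_tools(des))

  consensus <- NULL
  accuracy <- NULL
  if (length(predictions) >= config$min_tools) {
    consensus <- stage("consensus", build_consensus(predictions, min_tools = config$min_tools))
    if (nrow(consensus) > 0) {
      accuracy <- stage("accuracy", purrr::map_dfr(
        predictions, accuracy_vs_reference,
        reference = consensus
      ))
    }
  }

  out <- structure(
    list(
      tendency = tend, pairs = pairs, lists = lists, des = des,
      ranking = ranking, consensus = consensus, accuracy = accuracy,
      config = config
    ),
    class = "cci_benchmark"
  )
  if (!is.null(out_dir)) write_benchmark(out, out_dir)
  out
}

write_benchmark <- function(result, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  write_tendency(result$tendency, file.path(out_dir, "tendency.tsv"))
  write_pairs(result$pairs, file.path(out_dir, "pairs.tsv"))
  readr::write_tsv(bind_rows(purrr::map(result$des, as_tibble)),
    file.path(out_dir, "des_per_pair.tsv"))
  readr::write_tsv(result$ranking, file.path(out_dir, "des_ranking.tsv"))
  if (!is.null(result$consensus)) {
    readr::write_tsv(as_tibble(result$consensus), file.path(out_dir, "consensus.tsv"))
  }
  if (!is.null(result$accuracy)) {
    readr::write_tsv(as_tibble(result$accuracy), file.path(out_dir, "accuracy.tsv"))
  }
  summary <- list(
    tools = result$ranking$tool,
    mean_des = setNames(as.list(result$ranking$mean_des), result$ranking$tool),
    n_short = sum(result$tendency$range_class == "short"),
    n_long = sum(result$tendency$range_class == "long"),
    n_near = sum(result$pairs$pair_class == "near"),
    n_far = sum(result$pairs$pair_class == "far"),
    config = unclass(result$config)
  )
  jsonlite::write_json(summary, file.path(out_dir, "summary.json"),
    auto_unbox = TRUE, digits = NA, pretty = TRUE)
  log <- c(
    paste0("ccibench ", as.character(utils::packageVersion("ccibench"))),
    paste0("R ", R.version.string),
    paste0("seed: ", result$config$seed),
    paste0("parameters: ", jsonlite::toJSON(unclass(result$config), auto_unbox = TRUE))
  )
  writeLines(log, file.path(out_dir, "run_log.txt"))
  invisible(out_dir)
}

#' @export
print.cci_benchmark <- function(x, ...) {
  cat("<cci_benchmark>\n")
  cat(sprintf(
    "  interactions: %d scored (%d short, %d long)\n",
    nrow(x$tendency),
    sum(x$tendency$range_class == "short"),
    sum(x$tendency$range_class == "long")
  ))
  cat(sprintf(
    "  cell-type pairs: %d (%d near, %d far)\n", nrow(x$pairs),
    sum(x$pairs$pair_class == "near"), sum(x$pairs$pair_class == "far")
  ))
  cat("  tool ranking by mean DES:\n")
  print(as.data.frame(x$ranking), row.names = FALSE)
  invisible(x)
}
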