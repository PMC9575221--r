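#' Plot a gene's spatial expression distribution
#'
#' Spot map with point size/alpha proportional to the distribution weight
#' of a gene or complex.
#'
#' @param st A [spatial_expression()].
#' @param genes Gene symbol(s); complexes take the per-spot minimum.
#' @return A ggplot object.
#' @export
plot_gene_distribution <- function(st, genes) {
  d <- gene_distribution(st, genes)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$x, y = .data$y, size = .data$weight)) +
    ggplot2::geom_point(alpha = 0.7, colour = "#2c7fb8") +
    ggplot2::coord_equal() +
    ggplot2::labs(
      title = paste(genes, collapse = "+"),
      size = "mass"
    ) +
    ggplot2::theme_minimal()
}

#' @describeIn ccibench-autoplot d_ratio distribution with significant
#'   short/long-range interactions highlighted.
#' @method autoplot cci_tendency
#' @export
autoplot.cci_tendency <- function(object, ...) {
  dat <- as_tibble(object)
  if (!"range_class" %in% names(dat)) dat$range_class <- "medium"
  ggplot2::ggplot(dat, ggplot2::aes(x = .data$d_ratio, fill = .data$range_class)) +
    ggplot2::geom_histogram(bins = 30, colour = "grey30", linewidth = 0.2) +
    ggplot2::geom_vline(xintercept = 1, linetype = 2) +
    ggplot2::scale_fill_manual(values = c(
      short = "#1b9e77", medium = "grey80", long = "#d95f02"
    )) +
    ggplot2::labs(
      x = "distance ratio (observed / mean permuted)",
      y = "interactions", fill = "range"
    ) +
    ggplot2::theme_minimal()
}

#' Autoplot methods
#'
#' Quick diagnostic figures for the main result types.
#'
#' @param object The result object.
#' @param ... Unused.
#' @return A ggplot object.
#' @name ccibench-autoplot
NULL

#' @describeIn ccibench-autoplot cell-type pair distances coloured by
#'   near/medium/far class.
#' @method autoplot cci_pairs
#' @export
autoplot.cci_pairs <- function(object, ...) {
  dat <- as_tibble(object)
  dat$pair <- paste(dat$type_a, dat$type_b, sep = " - ")
  if (!"pair_class" %in% names(dat)) dat$pair_class <- "medium"
  ggplot2::ggplot(dat, ggplot2::aes(
    x = stats::reorder(.data$pair, .data$distance),
    y = .data$distance, fill = .data$pair_class
  )) +
    ggplot2::geom_col() +
    ggplot2::coord_flip() +
    ggplot2::scale_fill_manual(values = c(
      near = "#1b9e77", medium = "grey80", far = "#d95f02"
    )) +
    ggplot2::labs(x = NULL, y = "mean nearest-spot distance", fill = "class") +
    ggplot2::theme_minimal()
}

#' @describeIn ccibench-autoplot per-pair DES values for one tool.
#' @method autoplot cci_des
#' @export
autoplot.cci_des <- function(object, ...) {
  dat <- as_tibble(object)
  dat$pair <- paste(dat$type_a, dat$type_b, sep = " - ")
  ggplot2::ggplot(dat, ggplot2::aes(
    x = stats::reorder(.data$pair, .data$des),
    y = .data$des, fill = .data$pair_class
  )) +
    ggplot2::geom_col() +
    ggplot2::coord_flip() +
    ggplot2::ylim(0, 1) +
    ggplot2::scale_fill_manual(values = c(near = "#1b9e77", far = "#d95f02")) +
    ggplot2::labs(
      x = NULL, y = "distance enrichment score",
      title = attr(object, "tool"), fill = "pair class"
    ) +
    ggplot2::theme_minimal()
}

#' @describeIn ccibench-autoplot mean DES of every tool, ranked.
#' @method autoplot cci_benchmark
#' @export
autoplot.cci_benchmark <- function(object, ...) {
  dat <- object$ranking
  ggplot2::ggplot(dat, ggplot2::aes(
    x = stats::reorder(.data$tool, .data$mean_des), y = .data$mean_des
  )) +
    ggplot2::geom_col(fill = "#2c7fb8") +
    ggplot2::coord_flip() +
    ggplot2::ylim(0, 1) +
    ggplot2::labs(x = NULL, y = "mean distance enrichment score") +
    ggplot2::theme_minimal()
}
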