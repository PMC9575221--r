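#' Tidy and glance methods
#'
#' `tidy()` returns the per-unit table of a result (per interaction, per
#' cell-type pair, or per tool); `glance()` returns a one-row summary.
#'
#' @param x A `cci_tendency`, `cci_pairs`, `cci_des`, `cci_accuracy` or
#'   `cci_benchmark` object.
#' @param ... Unused.
#' @return A tibble.
#' @name ccibench-tidiers
NULL

#' @rdname ccibench-tidiers
#' @method tidy cci_tendency
#' @export
tidy.cci_tendency <- function(x, ...) as_tibble(x)

#' @rdname ccibench-tidiers
#' @method glance cci_tendency
#' @export
glance.cci_tendency <- function(x, ...) {
  cls <- if ("range_class" %in% names(x)) x$range_class else character(0)
  tibble(
    n_interactions = nrow(x),
    n_short = sum(cls == "short"), n_medium = sum(cls == "medium"),
    n_long = sum(cls == "long"),
    median_d_ratio = stats::median(x$d_ratio)
  )
}

#' @rdname ccibench-tidiers
#' @method tidy cci_des
#' @export
tidy.cci_des <- function(x, ...) as_tibble(x)

#' @rdname ccibench-tidiers
#' @method glance cci_des
#' @export
glance.cci_des <- function(x, ...) {
  tibble(
    tool = attr(x, "tool"), mean_des = attr(x, "mean_des"),
    n_pairs = nrow(x),
    n_near = sum(x$pair_class == "near"), n_far = sum(x$pair_class == "far")
  )
}

#' @rdname ccibench-tidiers
#' @method tidy cci_accuracy
#' @export
tidy.cci_accuracy <- function(x, ...) attr(x, "per_pair")

#' @rdname ccibench-tidiers
#' @method glance cci_accuracy
#' @export
glance.cci_accuracy <- function(x, ...) as_tibble(x)

#' @rdname ccibench-tidiers
#' @method tidy cci_benchmark
#' @export
tidy.cci_benchmark <- function(x, ...) x$ranking

#' @rdname ccibench-tidiers
#' @method glance cci_benchmark
#' @export
glance.cci_benchmark <- function(x, ...) {
  tibble(
    n_tools = nrow(x$ranking),
    n_interactions = nrow(x$tendency),
    n_short = sum(x$tendency$range_class == "short"),
    n_long = sum(x$tendency$range_class == "long"),
    n_near = sum(x$pairs$pair_class == "near"),
    n_far = sum(x$pairs$pair_class == "far"),
    best_tool = x$ranking$tool[1],
    best_mean_des = x$ranking$mean_des[1]
  )
}
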