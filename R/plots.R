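# ggplot2 views of the main result types.

#' Plot a TSS methylation profile
#'
#' @param profile Tibble from [tss_profile()].
#' @return A ggplot object: mean frequency against signed distance.
#' @export
plot_tss_profile <- function(profile) {
  ggplot2::ggplot(profile, ggplot2::aes(x = .data$offset, y = .data$mean_freq)) +
    ggplot2::geom_line(color = "#2166ac") +
    ggplot2::geom_point(size = 0.8) +
    ggplot2::labs(x = "distance from TSS (bp)", y = "mean methylation frequency") +
    ggplot2::theme_minimal()
}

#' Plot a coverage CCDF
#'
#' @param ccdf Tibble from [coverage_ccdf()] (optionally several,
#'   row-bound with a `method` column).
#' @return A ggplot object.
#' @export
plot_coverage_ccdf <- function(ccdf) {
  p <- if ("method" %in% names(ccdf)) {
    ggplot2::ggplot(ccdf, ggplot2::aes(x = .data$coverage, y = .data$ccdf,
                                       color = .data$method))
  } else {
    ggplot2::ggplot(ccdf, ggplot2::aes(x = .data$coverage, y = .data$ccdf))
  }
  p + ggplot2::geom_step() +
    ggplot2::labs(x = "strand-specific calling coverage",
                  y = "fraction of CpG sites at or above") +
    ggplot2::theme_minimal()
}

#' Plot the training loss history
#'
#' @param object A trained `sigmeth_model`.
#' @param ... Unused.
#' @return A ggplot object: loss components against training step.
#' @export
autoplot.sigmeth_model <- function(object, ...) {
  if (is.null(object$history)) stop_invalid("model has no training history")
  long <- tidyr::pivot_longer(
    dplyr::select(object$history, "step", "L_mod", "L_bases", "L_signal",
                  "L_diversity", "total"),
    -"step", names_to = "component", values_to = "loss")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$step, y = .data$loss,
                                     color = .data$component)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "step", y = "loss") +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Per-step training history of a fitted model
#'
#' @param x A trained `sigmeth_model`.
#' @param ... Unused.
#' @return The history tibble (one row per optimizer step).
#' @export
tidy.sigmeth_model <- function(x, ...) {
  if (is.null(x$history)) stop_invalid("model has no training history")
  dplyr::select(x$history, -"hard_usage")
}

#' One-row summary of a fitted model
#'
#' @param x A `sigmeth_model`.
#' @param ... Unused.
#' @return Tibble with the architecture dimensions, step count and final
#'   losses.
#' @export
glance.sigmeth_model <- function(x, ...) {
  cfg <- x$config
  last <- if (is.null(x$history)) NULL else x$history[nrow(x$history), ]
  tibble::tibble(
    mode = cfg$mode, f = cfg$f, H = cfg$H, L_enc = cfg$L_enc,
    L_dec = cfg$L_dec, d_ff = cfg$d_ff, l = cfg$l, b = cfg$b, K = cfg$K,
    n_steps = if (is.null(last)) 0L else last$step,
    final_total = if (is.null(last)) NA_real_ else last$total,
    final_L_mod = if (is.null(last)) NA_real_ else last$L_mod
  )
}

#' @importFrom rlang .data
NULL
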