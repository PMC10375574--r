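#' Plot a centroided spectrum
#'
#' @param spectrum A `spectrum`.
#' @param mz_range Optional zoom window.
#' @return A ggplot.
#' @export
plot_spectrum <- function(spectrum, mz_range = NULL) {
  dat <- spectrum
  if (!is.null(mz_range)) {
    dat <- dplyr::filter(dat, .data$mz >= mz_range[1], .data$mz <= mz_range[2])
  }
  ggplot2::ggplot(dat, ggplot2::aes(x = .data$mz, xend = .data$mz,
                                    y = 0, yend = .data$intensity)) +
    ggplot2::geom_segment() +
    ggplot2::labs(x = "m/z", y = "intensity") +
    ggplot2::theme_minimal()
}

#' Fragment coverage map
#'
#' One tile per (cleavage site, ion type) with accepted evidence filled.
#'
#' @param report A `coverage_report`.
#' @return A ggplot.
#' @export
plot_coverage <- function(report) {
  long <- tidyr::pivot_longer(report$positions, -"index",
                              names_to = "ion", values_to = "covered")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$index, y = .data$ion,
                                     fill = .data$covered)) +
    ggplot2::geom_tile(color = "white") +
    ggplot2::scale_fill_manual(values = c(`TRUE` = "#2a9d8f",
                                          `FALSE` = "grey85")) +
    ggplot2::labs(x = "cleavage site", y = NULL,
                  title = sprintf("%s: %.1f%% coverage",
                                  oligo_name(report$oligo), report$percent)) +
    ggplot2::theme_minimal()
}

#' Substitution discovery scores by site and type
#'
#' Bar chart of candidate scores labelled position/type, the standard view
#' of a single-base substitution discovery run.
#'
#' @param scores A `substitution_scores` tibble.
#' @param top_n Plot only the best `top_n` candidates (default 25).
#' @return A ggplot.
#' @export
plot_substitution_scores <- function(scores, top_n = 25) {
  dat <- utils::head(scores, top_n)
  dat$label <- sprintf("%d %s>%s", dat$position, dat$from_base, dat$to_base)
  dat$label <- factor(dat$label, levels = rev(dat$label))
  ggplot2::ggplot(dat, ggplot2::aes(x = .data$score, y = .data$label)) +
    ggplot2::geom_col(fill = "#264653") +
    ggplot2::labs(x = "score", y = "substitution") +
    ggplot2::theme_minimal()
}

#' Observed envelope against a fitted C/U mixture
#'
#' @param fit A `mixture_fit`.
#' @return A ggplot.
#' @export
plot_mixture_fit <- function(fit) {
  long <- tidyr::pivot_longer(fit$residuals, c("observed", "fitted"),
                              names_to = "which", values_to = "abundance")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$mz, xend = .data$mz, y = 0,
                                     yend = .data$abundance,
                                     color = .data$which)) +
    ggplot2::geom_segment(position = ggplot2::position_dodge(width = 0.02)) +
    ggplot2::labs(x = "m/z", y = "abundance",
                  title = sprintf("%.1f%% substitute, fit cosine %.3f",
                                  100 * fit$fraction_substitute,
                                  fit$fit_cosine)) +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' @method autoplot spectrum
#' @export
autoplot.spectrum <- function(object, ...) plot_spectrum(object, ...)

#' @method autoplot coverage_report
#' @export
autoplot.coverage_report <- function(object, ...) plot_coverage(object)

#' @method autoplot mixture_fit
#' @export
autoplot.mixture_fit <- function(object, ...) plot_mixture_fit(object)

#' @method autoplot substitution_scores
#' @export
autoplot.substitution_scores <- function(object, ...) {
  plot_substitution_scores(object, ...)
}
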