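# ggplot2 views of the main result types.

#' Plot a peak methylation-level histogram
#' @param distribution Output of [methylation_distribution()].
#' @return A ggplot.
#' @export
plot_methylation_distribution <- function(distribution) {
  ggplot2::ggplot(distribution,
                  ggplot2::aes(x = (.data$bin_start + .data$bin_end) / 2,
                               y = .data$count)) +
    ggplot2::geom_col(width = distribution$bin_end[1] -
                        distribution$bin_start[1],
                      fill = "grey30") +
    ggplot2::labs(x = "peak mean methylation level", y = "peaks") +
    ggplot2::theme_minimal()
}

#' @export
autoplot.methylation_profile <- function(object, ...) {
  ggplot2::ggplot(tibble::as_tibble(object),
                  ggplot2::aes(x = .data$offset, y = .data$mean_level)) +
    ggplot2::geom_line(color = "steelblue") +
    ggplot2::geom_vline(xintercept = 0, linetype = "dashed",
                        color = "grey50") +
    ggplot2::labs(x = "offset from site center (bp)",
                  y = "mean methylation level") +
    ggplot2::theme_minimal()
}

#' Plot methylation metaplots for several site groups
#' @param profiles Named list of `"methylation_profile"`s.
#' @return A ggplot.
#' @export
plot_flank_profiles <- function(profiles) {
  df <- purrr::imap_dfr(profiles, function(p, nm) {
    tibble(offset = p$offset, mean_level = p$mean_level, group = nm)
  })
  ggplot2::ggplot(df, ggplot2::aes(x = .data$offset, y = .data$mean_level,
                                   color = .data$group)) +
    ggplot2::geom_line() +
    ggplot2::geom_vline(xintercept = 0, linetype = "dashed",
                        color = "grey50") +
    ggplot2::labs(x = "offset from site center (bp)",
                  y = "mean methylation level") +
    ggplot2::theme_minimal()
}

#' Plot chromatin-state composition per methylation group
#' @param composition Output of [state_composition()].
#' @return A ggplot.
#' @export
plot_state_composition <- function(composition) {
  ggplot2::ggplot(composition,
                  ggplot2::aes(x = .data$group, y = .data$fraction,
                               fill = .data$state)) +
    ggplot2::geom_col() +
    ggplot2::labs(x = "methylation group", y = "fraction of peaks") +
    ggplot2::theme_minimal()
}

#' @export
autoplot.pwm <- function(object, ...) {
  df <- tidy(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$position,
                                   y = .data$probability,
                                   fill = .data$base)) +
    ggplot2::geom_col() +
    ggplot2::labs(x = "motif position", y = "base probability") +
    ggplot2::theme_minimal()
}

#' @export
autoplot.methyl_motif <- function(object, ...) {
  df <- tidy(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$position,
                                   y = .data$frequency,
                                   fill = .data$base)) +
    ggplot2::geom_col() +
    ggplot2::scale_fill_manual(values = c(
      A = "#109648", C = "#255C99", G = "#F7B32B", T = "#D62839",
      E = "#7B2CBF"
    )) +
    ggplot2::labs(x = "motif position", y = "letter frequency") +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
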