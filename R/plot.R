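#' Plot a response trace
#'
#' @param object A `"tgf_trace"`.
#' @param ... Unused.
#' @return A ggplot: nuclear heterodimer concentration over time.
#' @method autoplot tgf_trace
#' @export
autoplot.tgf_trace <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$time_s / 3600,
                                       y = .data$output_pM)) +
    ggplot2::geom_line(colour = "#B2182B") +
    ggplot2::labs(x = "time after stimulation (h)",
                  y = "nuclear R-Smad/Co-Smad complex (pM)") +
    ggplot2::theme_minimal()
}

#' Plot the label composition of a screen
#'
#' @param object A `"tgf_screen"`.
#' @param ... Unused.
#' @return A ggplot: fraction of parameter sets per response label.
#' @method autoplot tgf_screen
#' @export
autoplot.tgf_screen <- function(object, ...) {
  fr <- summarize_fractions(object)
  fr$label <- factor(fr$label, levels = response_labels())
  ggplot2::ggplot(fr, ggplot2::aes(x = .data$label, y = .data$fraction)) +
    ggplot2::geom_col(fill = "grey35") +
    ggplot2::labs(x = NULL, y = "fraction of parameter sets") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 30,
                                                       hjust = 1))
}

#' Plot a fitted dose-response saturation curve
#'
#' @param object A `"saturation_fit"`.
#' @param ... Unused.
#' @return A ggplot: peak output versus dose (log x) with the fitted
#'   exponential saturation curve.
#' @method autoplot saturation_fit
#' @export
autoplot.saturation_fit <- function(object, ...) {
  d <- object$data
  g <- ggplot2::ggplot(d, ggplot2::aes(x = .data$dose_pM,
                                       y = .data$Opeak_pM)) +
    ggplot2::geom_point() +
    ggplot2::scale_x_log10() +
    ggplot2::labs(x = "TGF-beta dose (pM)", y = "peak output (pM)") +
    ggplot2::theme_minimal()
  if (identical(object$status, "ok")) {
    xs <- exp(seq(log(min(d$dose_pM)), log(max(d$dose_pM)), length.out = 200))
    curve <- tibble::tibble(
      dose_pM = xs,
      Opeak_pM = object$max_peak_pM * (1 - exp(-xs / object$eta_pM))
    )
    g <- g + ggplot2::geom_line(data = curve, colour = "#2166AC")
  }
  g
}

#' Phenotype segregation in the feedback/dephosphorylation plane
#'
#' Scatter of the composite features of [derived_features()] (log-log) for
#' the classified parameter sets of a screen, coloured by response label.
#' Transient sets concentrate at strong feedback and fast dephosphorylation
#' relative to sustained sets.
#'
#' @param screen A `"tgf_screen"`.
#' @param x,y Feature columns to span the plane (defaults `F` and `D`).
#' @param labels Labels to show (default the classified phenotypes).
#' @return A ggplot.
#' @export
plot_feature_plane <- function(screen, x = "F", y = "D",
                               labels = c("sustained", "transient",
                                          "dampened_oscillatory",
                                          "sustained_oscillatory")) {
  d <- dplyr::filter(screen, .data$label %in% labels)
  ggplot2::ggplot(d, ggplot2::aes(x = .data[[x]], y = .data[[y]],
                                  colour = .data$label)) +
    ggplot2::geom_point(alpha = 0.5, size = 0.8) +
    ggplot2::scale_x_log10() +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = paste("composite feature", x),
                  y = paste("composite feature", y)) +
    ggplot2::theme_minimal()
}
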