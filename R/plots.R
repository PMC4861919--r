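# ggplot2 views of the main result types.

#' Per-exon copy-number profile plot
#'
#' Horizontal-bar rendering of per-exon log2 copy-number ratios, one row per
#' sample: amplified exons above the threshold show up as the stepped
#' profile characteristic of an intragenic breakpoint.
#'
#' @param object An `exon_cn` tibble from [exon_copy_number()].
#' @param t_amp Threshold drawn as a reference line, default 0.3.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.exon_cn <- function(object, t_amp = 0.3, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = factor(.data$exon), y = .data$log2)) +
    ggplot2::geom_col(ggplot2::aes(fill = .data$log2 >= t_amp)) +
    ggplot2::geom_hline(yintercept = t_amp, linetype = "dashed") +
    ggplot2::facet_wrap(ggplot2::vars(.data$sample)) +
    ggplot2::scale_fill_manual(values = c(`TRUE` = "#b2182b", `FALSE` = "#2166ac"),
                               guide = "none") +
    ggplot2::labs(x = "exon (transcript order)", y = "log2 copy-number ratio")
}

#' Amplification recurrence profile plot
#'
#' @param object A `freq_profile` tibble from [amplification_frequency()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.freq_profile <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = (.data$start + .data$end) / 2e6,
                                       y = .data$fraction)) +
    ggplot2::geom_step() +
    ggplot2::facet_wrap(ggplot2::vars(.data$chromosome), scales = "free_x") +
    ggplot2::labs(x = "position (Mb)", y = "amplified fraction of samples")
}

#' Per-sample block-ratio plot of a fold comparison
#'
#' Dot plot of the per-sample 5':3' log2 expression ratios by group, with
#' group geometric-mean folds as crossbars.
#'
#' @param object A `fold_comparison` object.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.fold_comparison <- function(object, ...) {
  means <- tibble(
    group = c("truncated", "control"),
    r = c(log2(object$f_truncated), log2(object$f_control))
  )
  ggplot2::ggplot(object$ratios, ggplot2::aes(x = .data$group, y = .data$r)) +
    ggplot2::geom_jitter(width = 0.08, height = 0, alpha = 0.7) +
    ggplot2::geom_crossbar(data = means,
                           ggplot2::aes(ymin = .data$r, ymax = .data$r),
                           width = 0.4, color = "#b2182b") +
    ggplot2::labs(x = NULL, y = "5':3' exon-block log2 ratio")
}
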