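#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

outcome_palette <- c(wild_type = "#9ecae1", deletion = "#de2d26",
                     insertion = "#08519c", complex = "#d8c99b")

#' Stacked per-IR outcome-frequency bars
#'
#' One bar per IR, bands for the fraction of molecules per repair outcome,
#' faceted by assay.
#'
#' @param profiles tibble from [compute_profiles()].
#' @return a ggplot object.
#' @export
plot_outcome_profiles <- function(profiles) {
  long <- profiles %>%
    tidyr::pivot_longer(cols = c("wild_type", "deletion", "insertion",
                                 "complex"),
                        names_to = "outcome", values_to = "freq") %>%
    mutate(outcome = factor(.data$outcome,
                            levels = c("complex", "insertion", "deletion",
                                       "wild_type")))
  ggplot2::ggplot(long, ggplot2::aes(x = .data$barcode, y = .data$freq,
                                     fill = .data$outcome)) +
    ggplot2::geom_col(width = 1) +
    ggplot2::scale_fill_manual(values = outcome_palette) +
    ggplot2::facet_wrap(~assay, ncol = 1) +
    ggplot2::labs(x = "integrated reporter", y = "fraction of molecules",
                  fill = "outcome") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_blank(),
                   panel.grid.major.x = ggplot2::element_blank())
}

#' Per-junction insertion counts after redistribution
#'
#' Grouped bars of unambiguous plus redistributed 1-bp insertion counts per
#' junction and base, with the 3|4 and 4|5 break sites shaded.
#'
#' @param redistributed tibble from [redistribute_counts()].
#' @param log_scale use a log10 count axis (default TRUE, matching how
#'   these profiles are usually displayed).
#' @return a ggplot object.
#' @export
plot_insertion_counts <- function(redistributed, log_scale = TRUE) {
  dat <- redistributed %>%
    mutate(junction_label = sprintf("%d|%d", .data$junction,
                                    .data$junction + 1L))
  p <- ggplot2::ggplot(dat,
                       ggplot2::aes(x = stats::reorder(.data$junction_label,
                                                       -.data$junction),
                                    y = .data$count, fill = .data$base)) +
    ggplot2::annotate("rect", xmin = which(sort(unique(dat$junction),
                                                decreasing = TRUE) == 4L) - 0.5,
                      xmax = which(sort(unique(dat$junction),
                                        decreasing = TRUE) == 3L) + 0.5,
                      ymin = -Inf, ymax = Inf, alpha = 0.15) +
    ggplot2::geom_col(position = ggplot2::position_dodge(width = 0.8),
                      width = 0.7) +
    ggplot2::scale_fill_brewer(palette = "Set1") +
    ggplot2::labs(x = "junction (upstream of PAM, ntDNA)",
                  y = "insertion count", fill = "inserted base") +
    ggplot2::theme_minimal()
  if (log_scale) p <- p + ggplot2::scale_y_log10()
  p
}

#' Effect-size (eta-squared) bars
#'
#' @param object a [fit_effect_model()] result.
#' @param ... unused.
#' @return a ggplot object.
#' @export
autoplot.cas9_effect_fit <- function(object, ...) {
  dat <- object$anova %>%
    mutate(term = stats::reorder(.data$term, .data$eta_sq))
  ggplot2::ggplot(dat, ggplot2::aes(x = .data$term, y = .data$eta_sq)) +
    ggplot2::geom_col(fill = "#4477aa") +
    ggplot2::coord_flip() +
    ggplot2::labs(x = NULL, y = expression(eta^2),
                  subtitle = sprintf("model R^2 = %.3f", object$r_squared)) +
    ggplot2::theme_minimal()
}

#' Knock-in / error-insertion ratio against binned mutation frequency
#'
#' @param binned tibble from [knockin_ratio_binned()].
#' @return a ggplot object.
#' @export
plot_knockin_ratio <- function(binned) {
  dat <- binned %>% filter(!is.na(.data$mean_ratio))
  ggplot2::ggplot(dat, ggplot2::aes(x = .data$bin_mid, y = .data$mean_ratio)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$conf_low,
                                      ymax = .data$conf_high),
                         fill = "#74a9cf", alpha = 0.4) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::geom_hline(yintercept = 1, linetype = 2) +
    ggplot2::labs(x = "total IR mutation frequency (binned)",
                  y = "knock-in / error-insertion ratio") +
    ggplot2::theme_minimal()
}

#' Ranked DNA end-structure frequencies
#'
#' Horizontal bars for the most frequent end-structure groups recovered
#' from hairpin-capture reads.
#'
#' @param ranked tibble from [match_and_rank()].
#' @param top number of groups to show (default 10).
#' @return a ggplot object.
#' @export
plot_end_structures <- function(ranked, top = 10L) {
  dat <- head(ranked, top) %>%
    mutate(label = stats::reorder(stringr::str_trunc(.data$label, 40),
                                  .data$freq))
  ggplot2::ggplot(dat, ggplot2::aes(x = .data$freq, y = .data$label,
                                    fill = .data$class)) +
    ggplot2::geom_col() +
    ggplot2::labs(x = "relative frequency", y = NULL, fill = "structure") +
    ggplot2::theme_minimal()
}
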