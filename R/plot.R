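#' Plot a dispersion scan
#'
#' Per-marker `-log10(P)` of the joint genotype test against physical
#' position, faceted by chromosome, with the FDR-with-floor rejections
#' highlighted and the nominal hard floor drawn as a reference line.
#'
#' @param object A `pd_scan`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot pd_scan
#' @export
autoplot.pd_scan <- function(object, ...) {
  tab <- object$table
  if (!nrow(tab)) abort("empty scan table")
  tab$chr <- factor(tab$chr, levels = unique(tab$chr[order(chr_order(tab$chr))]))
  ggplot2::ggplot(tab, ggplot2::aes(x = .data$mb, y = -log10(.data$p_joint))) +
    ggplot2::geom_hline(yintercept = -log10(object$config$floor),
                        linetype = "dashed", colour = "grey50") +
    ggplot2::geom_point(ggplot2::aes(colour = .data$reject), size = 1.4) +
    ggplot2::scale_colour_manual(values = c(`FALSE` = "grey30",
                                            `TRUE` = "firebrick"),
                                 name = "FDR reject") +
    ggplot2::facet_grid(. ~ chr, scales = "free_x", space = "free_x") +
    ggplot2::labs(
      x = "position (Mb)",
      y = expression(-log[10](italic(P))),
      title = paste0("Dispersion scan: ", object$trait,
                     " (", object$cohort, ")")
    ) +
    ggplot2::theme_bw() +
    ggplot2::theme(panel.spacing = ggplot2::unit(0.1, "lines"),
                   axis.text.x = ggplot2::element_blank(),
                   axis.ticks.x = ggplot2::element_blank())
}

#' Plot fitted genotype-class dispersion means
#'
#' Point-and-interval display of the fitted per-genotype dispersion means
#' (+/- 1 SE) underlying an architecture call.
#'
#' @param object An `architecture_call`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot architecture_call
#' @export
autoplot.architecture_call <- function(object, ...) {
  mm <- object$means
  mm$class <- factor(mm$class, levels = c("hom_p1", "het", "hom_p2"),
                     labels = mm$strain)
  lab <- if (nrow(object$labels)) {
    paste(object$labels$form, collapse = ", ")
  } else "no label"
  ggplot2::ggplot(mm, ggplot2::aes(x = .data$class, y = .data$estimate)) +
    ggplot2::geom_pointrange(ggplot2::aes(
      ymin = .data$estimate - .data$std.error,
      ymax = .data$estimate + .data$std.error
    )) +
    ggplot2::labs(x = "genotype", y = "fitted dispersion (PD)",
                  title = paste0("Architecture: ", lab)) +
    ggplot2::theme_bw()
}
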