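# ggplot2 graphics for the package's result objects.

#' Plot an NMDS ordination with optional fitted vectors
#'
#' @param object A `litter_nmds` object.
#' @param groups Optional vector (aligned with the ordination rows) used to
#'   colour points, e.g. the streambed compartment.
#' @param vectors Optional [fit_vectors()] tibble; significant continuous
#'   vectors are drawn as arrows scaled by `sqrt(r2)`, factor centroids as
#'   labels.
#' @param alpha Significance threshold for drawing a fitted variable
#'   (default 0.05).
#' @param arrow_scale Arrow length multiplier (default chosen from the
#'   spread of the configuration).
#' @param ... Unused.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.litter_nmds <- function(object, groups = NULL, vectors = NULL,
                                 alpha = 0.05, arrow_scale = NULL, ...) {
  pts <- object$points
  p <- if (is.null(groups)) {
    ggplot2::ggplot(pts, ggplot2::aes(x = .data$NMDS1, y = .data$NMDS2)) +
      ggplot2::geom_point(size = 2)
  } else {
    pts$group <- groups
    ggplot2::ggplot(pts, ggplot2::aes(x = .data$NMDS1, y = .data$NMDS2,
                                      colour = .data$group)) +
      ggplot2::geom_point(size = 2) +
      ggplot2::labs(colour = NULL)
  }
  if (!is.null(vectors)) {
    arrow_scale <- arrow_scale %||%
      (0.9 * max(abs(c(pts$NMDS1, pts$NMDS2))))
    vec <- vectors %>% filter(.data$type == "vector",
                              .data$p_perm < alpha, !.data$constant)
    if (nrow(vec)) {
      vec <- vec %>% mutate(xend = .data$NMDS1 * sqrt(.data$r2) * arrow_scale,
                            yend = .data$NMDS2 * sqrt(.data$r2) * arrow_scale)
      p <- p +
        ggplot2::geom_segment(
          data = vec,
          ggplot2::aes(x = 0, y = 0, xend = .data$xend, yend = .data$yend),
          inherit.aes = FALSE,
          arrow = ggplot2::arrow(length = ggplot2::unit(2, "mm"))) +
        ggplot2::geom_text(
          data = vec,
          ggplot2::aes(x = .data$xend * 1.08, y = .data$yend * 1.08,
                       label = .data$variable),
          inherit.aes = FALSE, size = 3)
    }
    cent <- vectors %>% filter(.data$type == "factor", .data$p_perm < alpha)
    if (nrow(cent)) {
      p <- p + ggplot2::geom_text(
        data = cent,
        ggplot2::aes(x = .data$NMDS1, y = .data$NMDS2, label = .data$level),
        inherit.aes = FALSE, fontface = "bold", size = 3.5)
    }
  }
  p + ggplot2::labs(
    subtitle = sprintf("stress = %.3f, non-metric R2 = %.3f",
                       object$stress, object$nonmetric_r2)) +
    ggplot2::theme_minimal()
}

#' Plot the effect decomposition of a mediation fit
#'
#' Forest-style plot of the total effect, direct effect and per-mediator
#' `a`/`b` paths with approximate 95% intervals.
#'
#' @param object A `litter_mediation` object.
#' @param ... Unused.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.litter_mediation <- function(object, ...) {
  td <- tidy(object) %>%
    mutate(label = dplyr::case_when(
      .data$path == "c" ~ "total (c)",
      .data$path == "c_prime" ~ "direct (c')",
      TRUE ~ paste0(.data$path, ": ", .data$mediator)))
  sub <- if (is.na(object$proportion_mediated)) {
    "total effect not significant"
  } else {
    sprintf("proportion mediated = %.2f [%.2f, %.2f] (%s)",
            object$proportion_mediated, object$proportion_ci[1],
            object$proportion_ci[2], object$classification)
  }
  ggplot2::ggplot(td, ggplot2::aes(x = .data$estimate,
                                   y = stats::reorder(.data$label,
                                                      .data$estimate))) +
    ggplot2::geom_vline(xintercept = 0, linetype = 2, colour = "grey60") +
    ggplot2::geom_errorbarh(
      ggplot2::aes(xmin = .data$estimate - 1.96 * .data$se,
                   xmax = .data$estimate + 1.96 * .data$se),
      height = 0.2) +
    ggplot2::geom_point() +
    ggplot2::labs(x = "standardized coefficient", y = NULL,
                  title = object$response, subtitle = sub) +
    ggplot2::theme_minimal()
}

#' Compartment comparison of decay metrics
#'
#' Boxplots of decay coefficients (scaled to 1e-3 per degree-day, the usual
#' reporting unit) and the stabilization factor, by streambed compartment.
#'
#' @param decay A [decay_table()] tibble.
#' @return A ggplot object.
#' @export
plot_decay_by_zone <- function(decay) {
  assert_cols(decay, c("zone", "k_green", "k_red", "k_cotton", "S"))
  long <- decay %>%
    mutate(k_green = 1e3 * .data$k_green, k_red = 1e3 * .data$k_red,
           k_cotton = 1e3 * .data$k_cotton) %>%
    tidyr::pivot_longer(c("k_cotton", "k_green", "k_red", "S"),
                        names_to = "metric", values_to = "value")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$zone, y = .data$value,
                                     fill = .data$zone)) +
    ggplot2::geom_boxplot(show.legend = FALSE) +
    ggplot2::facet_wrap(~metric, scales = "free_y") +
    ggplot2::labs(x = NULL,
                  y = "k (1e-3 per degree-day) / S (unitless)") +
    ggplot2::theme_minimal()
}
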