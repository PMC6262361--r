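# ggplot2 visualisations for the main result types.

#' Plot expression data, optionally with model solutions
#'
#' Points and error bars are the observed means +/- s.d.; lines are model
#' trajectories when a solution tibble is supplied.
#'
#' @param data An expression tibble.
#' @param solution Optional solution tibble (`condition`, `gene`, `time`,
#'   `value`).
#' @param genes Genes to show.
#' @return A ggplot object.
#' @export
plot_expression_data <- function(data, solution = NULL,
                                 genes = target_genes()) {
  d <- data[data$gene %in% genes, ]
  p <- ggplot2::ggplot(d, ggplot2::aes(x = .data$time, y = .data$mean)) +
    ggplot2::geom_errorbar(ggplot2::aes(ymin = pmax(.data$mean - .data$sd, 0),
                                        ymax = .data$mean + .data$sd),
                           width = 0.3, colour = "grey40") +
    ggplot2::geom_point(size = 1.2) +
    ggplot2::facet_grid(gene ~ condition, scales = "free_y") +
    ggplot2::labs(x = "days after sowing", y = "relative expression")
  if (!is.null(solution)) {
    s <- combine_solutions(solution)
    s <- s[s$gene %in% genes, ]
    p <- p + ggplot2::geom_line(data = s,
                                ggplot2::aes(y = .data$value),
                                colour = "firebrick")
  }
  p
}

#' @export
autoplot.grn_fit <- function(object, data = NULL, ...) {
  if (is.null(data)) {
    abort("autoplot.grn_fit needs the fitted dataset via `data =`")
  }
  plot_expression_data(data, object$solution)
}

#' @export
autoplot.grn_ensemble <- function(object, ...) {
  costs <- tibble::tibble(cost = ensemble_costs(object))
  ggplot2::ggplot(costs, ggplot2::aes(x = "", y = .data$cost)) +
    ggplot2::geom_boxplot(width = 0.4, outlier.shape = 16) +
    ggplot2::labs(x = NULL, y = "wRSS",
                  title = paste0("Cost distribution (",
                                 object$spec$hypothesis,
                                 if (!is.null(object$spec$singled_ft))
                                   paste0(", ", object$spec$singled_ft), ")"))
}

#' @export
autoplot.regulation_summary <- function(object, ...) {
  th <- attr(object, "thresholds") %||% c(0.05, 0.95)
  ggplot2::ggplot(object, ggplot2::aes(x = .data$edge, y = .data$value)) +
    ggplot2::geom_boxplot(outlier.shape = 16) +
    ggplot2::geom_hline(yintercept = th, linetype = "dashed",
                        colour = "grey50") +
    ggplot2::coord_cartesian(ylim = c(0, 1)) +
    ggplot2::labs(x = NULL, y = "time-averaged regulation function") +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45,
                                                       hjust = 1))
}

#' Bar chart of AICc relative to the baseline hypothesis
#'
#' @param screen A `grn_screen`.
#' @return A ggplot object.
#' @export
plot_hypothesis_screen <- function(screen) {
  tab <- tibble::as_tibble(screen)
  ggplot2::ggplot(tab, ggplot2::aes(x = .data$model, y = .data$aicc_rel)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::geom_hline(yintercept = 1, linetype = "dashed") +
    ggplot2::labs(x = NULL, y = "AICc / AICc(H0)")
}
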