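# ggplot2 views of structures, ensembles and switch reports.

#' @importFrom ggplot2 autoplot ggplot aes geom_curve geom_point geom_tile
#'   geom_col geom_hline scale_fill_gradient labs theme_minimal coord_fixed
NULL

#' Arc diagram of a folded structure
#'
#' @param object `mir_structure`.
#' @param ... ignored.
#' @return ggplot.
#' @export
autoplot.mir_structure <- function(object, ...) {
  pairs <- object$pairs
  n <- nchar(object$sequence)
  base <- tibble::tibble(x = seq_len(n))
  p <- ggplot(base, aes(x = .data$x, y = 0)) +
    geom_point(size = 0.4, colour = "grey40")
  if (nrow(pairs) > 0) {
    p <- p + geom_curve(
      data = pairs,
      aes(x = .data$i, xend = .data$j, y = 0, yend = 0),
      curvature = -0.6, linewidth = 0.3, colour = "steelblue",
      inherit.aes = FALSE
    )
  }
  p + labs(x = "position", y = NULL,
           title = sprintf("MFE structure, dG = %.2f kcal/mol", object$delta_g)) +
    theme_minimal() +
    ggplot2::theme(axis.text.y = ggplot2::element_blank(),
                   panel.grid = ggplot2::element_blank())
}

#' Base-pair probability dot plot
#'
#' @param object `mir_ensemble`.
#' @param cutoff probabilities below this are not drawn.
#' @param ... ignored.
#' @return ggplot.
#' @export
autoplot.mir_ensemble <- function(object, cutoff = 0.01, ...) {
  df <- tidy(object)
  df <- df[df$probability >= cutoff, ]
  ggplot(df, aes(x = .data$j, y = .data$i, fill = .data$probability)) +
    geom_tile() +
    scale_fill_gradient(low = "grey90", high = "firebrick", limits = c(0, 1)) +
    coord_fixed() +
    labs(x = "position j", y = "position i", fill = "P(i:j)",
         title = "equilibrium base-pair probabilities") +
    theme_minimal()
}

#' Designed-pair probabilities of a switch report
#'
#' Bars give the equilibrium probability of every designed (non-mismatch)
#' stem pair; the dashed line marks the design target.
#'
#' @param object `mir_switch_report`.
#' @param target probability target (default from the design constraints).
#' @param ... ignored.
#' @return ggplot.
#' @export
autoplot.mir_switch_report <- function(object, target = NULL, ...) {
  target <- target %||% object$design$constraints$pair_prob_target
  df <- object$stem_pair_probabilities
  ggplot(df, aes(x = .data$arm_pos, y = .data$probability)) +
    geom_col(fill = "steelblue") +
    geom_hline(yintercept = target, linetype = "dashed", colour = "firebrick") +
    labs(x = "arm position (5'->3' along the sequestered arm)",
         y = "pair probability",
         title = sprintf("designed stem pairs (OFF state), median %.2f",
                         stats::median(df$probability))) +
    theme_minimal()
}

#' Summary plot for a batch of switch reports
#'
#' @param reports list of `mir_switch_report`.
#' @return ggplot of OFF sequestration vs. ON gain, coloured by pass/fail.
#' @export
plot_switch_summary <- function(reports) {
  df <- dplyr::bind_rows(purrr::map(reports, glance))
  df$pass <- purrr::map_lgl(reports, ~ switch_score(.x)$pass)
  ggplot(df, aes(x = .data$off_spacer_paired_fraction, y = .data$on_gain,
                 colour = .data$pass)) +
    geom_point(size = 2) +
    labs(x = "OFF spacer paired fraction", y = "ON gain",
         colour = "passes") +
    theme_minimal()
}
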