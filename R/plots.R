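# ggplot2 visualisations of the main result types.

#' @importFrom ggplot2 autoplot ggplot aes geom_col geom_point geom_errorbar
#'   geom_hline geom_line labs coord_flip theme_minimal
#' @export
ggplot2::autoplot

#' Normalized change-difference bar plot
#'
#' Plots, for each variable of a [did_table()] result, the difference
#' between the normalized (Z-unit, sign-aligned) change of the biofortified
#' group and that of the comparison group; bars above zero mean the
#' biofortified group improved more.
#'
#' @param did A tibble from [did_table()].
#' @returns A ggplot object.
#' @export
plot_change_differences <- function(did) {
  if (!"z_change_difference" %in% names(did)) {
    abort("`did` must come from did_table().")
  }
  ggplot(did, aes(x = stats::reorder(.data$variable,
                                     .data$z_change_difference),
                  y = .data$z_change_difference)) +
    geom_col(fill = "steelblue") +
    geom_hline(yintercept = 0, linewidth = 0.3) +
    coord_flip() +
    labs(x = NULL, y = "normalized change difference (BPM - CPM, Z units)") +
    theme_minimal()
}

#' @export
autoplot.mediation_fit <- function(object, ...) {
  eff <- if (!is.null(object$boot)) object$boot$intervals else
    mutate(object$effects, conf_low = NA_real_, conf_high = NA_real_)
  ggplot(eff, aes(x = .data$effect, y = .data$estimate)) +
    geom_point(size = 2) +
    geom_errorbar(aes(ymin = .data$conf_low, ymax = .data$conf_high),
                  width = 0.15, na.rm = TRUE) +
    geom_hline(yintercept = 0, linetype = 2, linewidth = 0.3) +
    labs(x = NULL, y = "effect (Z units)",
         title = sprintf("%s → %s → %s (moderated by %s)",
                         object$spec$x, object$spec$m, object$spec$y,
                         object$spec$w)) +
    theme_minimal()
}

#' @export
autoplot.erp_epochs <- function(object, ...) {
  avg <- colMeans(object$data)
  ggplot(tibble(time_ms = object$times * 1000, amplitude = avg),
         aes(x = .data$time_ms, y = .data$amplitude)) +
    geom_line() +
    geom_hline(yintercept = 0, linewidth = 0.2) +
    labs(x = "time (ms)", y = "amplitude (µV)",
         title = "trial-averaged epoch") +
    theme_minimal()
}
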