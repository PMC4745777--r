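#' IC50 strip plot for a screened panel
#'
#' One point per cell line and condition on a log10 IC50 axis, with dashed
#' guide lines at the sensitivity thresholds (2 and 10 uM by default).
#' Censored IC50s are drawn at their censoring bound with an open symbol.
#'
#' @param panel A `panel_result`.
#' @param conditions Condition keys to include (default: all).
#' @return A ggplot object.
#' @export
plot_ic50_panel <- function(panel, conditions = NULL) {
  stopifnot(inherits(panel, "panel_result"))
  if (!requireNamespace("ggplot2", quietly = TRUE))
    stop("plot_ic50_panel requires the ggplot2 package", call. = FALSE)
  f <- panel$fits[!is.na(panel$fits$ic50_uM), ]
  f$key <- condition_key(f$condition, f$ratio)
  if (!is.null(conditions)) f <- f[f$key %in% conditions, ]
  cfg <- panel$config
  ggplot2::ggplot(f, ggplot2::aes(x = .data$key, y = .data$ic50_uM,
                                  shape = .data$censored)) +
    ggplot2::geom_jitter(width = 0.15, height = 0) +
    ggplot2::geom_hline(yintercept = c(cfg$sensitive_uM, cfg$resistant_uM),
                        linetype = "dashed") +
    ggplot2::scale_y_log10() +
    ggplot2::scale_shape_manual(values = c(`FALSE` = 16, `TRUE` = 1)) +
    ggplot2::labs(x = NULL, y = "IC50 (uM)", shape = "censored")
}

#' Combination-index box plot for a screened panel
#'
#' One box per ratio over the per-line median CI(E50-80) values, with
#' dashed guide lines at the additive band edges (0.8 and 1.2 by default).
#'
#' @param panel A `panel_result`.
#' @return A ggplot object.
#' @export
plot_ci_panel <- function(panel) {
  stopifnot(inherits(panel, "panel_result"))
  if (!requireNamespace("ggplot2", quietly = TRUE))
    stop("plot_ci_panel requires the ggplot2 package", call. = FALSE)
  ci <- panel$ci[!is.na(panel$ci$median_ci), ]
  ci$ratio_lab <- paste0(format(ci$ratio), ":1")
  bands <- panel$config$ci_bands
  ggplot2::ggplot(ci, ggplot2::aes(x = .data$ratio_lab,
                                   y = .data$median_ci)) +
    ggplot2::geom_boxplot() +
    ggplot2::geom_hline(yintercept = bands[2:3], linetype = "dashed") +
    ggplot2::labs(x = "PD:AZ ratio", y = "median CI (E50-E80)")
}
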