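#' Fixed-ratio (ray) combination design
#'
#' In a ray design the two drugs are mixed at a constant concentration ratio
#' `r` = PD:AZ while the total dose varies. The combination dose-response
#' curve is parameterised on the AZ-component concentration axis: at
#' AZ-component dose `d_AZ` the PD component is `d_PD = r * d_AZ` and the
#' total drug concentration is `(1 + r) * d_AZ`.
#'
#' @param r Positive PD:AZ concentration ratio. May also be given as a
#'   string such as `"0.25:1"`.
#' @return A list of class `fixed_ratio_design` with elements `r` and
#'   `dose_axis` (always `"AZ"`).
#' @export
fixed_ratio_design <- function(r) {
  r <- parse_ratio(r)
  if (!is.finite(r) || r <= 0)
    stop("ratio r must be a finite positive number", call. = FALSE)
  structure(list(r = r, dose_axis = "AZ"), class = "fixed_ratio_design")
}

#' Parse a "PD:AZ" ratio label
#'
#' Accepts numeric input (returned as-is) or strings like `"0.25:1"` and
#' `"4:1"`, returning PD/AZ as a number.
#' @param x Numeric or character scalar.
#' @return Numeric ratio.
#' @export
parse_ratio <- function(x) {
  if (is.numeric(x)) return(as.numeric(x))
  parts <- strsplit(as.character(x), ":", fixed = TRUE)[[1]]
  if (length(parts) == 1L) return(as.numeric(parts))
  as.numeric(parts[1]) / as.numeric(parts[2])
}

#' Loewe combination index at one effect level
#'
#' For growth-inhibition level `y`, reads the combination AZ-component dose
#' `d_AZ` achieving `y` off the combination fit, sets `d_PD = r * d_AZ`, and
#' the single-agent doses `D_PD`, `D_AZ` off the single-agent fits, then
#' \deqn{CI(E_y) = d_{PD}/D_{PD} + d_{AZ}/D_{AZ}.}
#' CI below 1 indicates Loewe synergy, 1 additivity, above 1 antagonism.
#'
#' Censoring: if any required dose is unattainable (the level exceeds a
#' curve's maximum inhibition), `censoring = "unattainable"` and `ci` is
#' `NA`. If a single-agent dose is censored at the extrapolation limit the
#' CI is computed with the limit value and flagged `"upper_bound"` (the true
#' CI can only be smaller). A censored combination dose means the
#' combination itself never reached the effect within its admissible range
#' and is treated as unattainable.
#'
#' @param fit_pd,fit_az Converged single-agent `four_pl_fit`s (dose axes:
#'   each drug's own concentration).
#' @param fit_combo Converged `four_pl_fit` of the combination on the
#'   AZ-component dose axis.
#' @param design A [fixed_ratio_design()].
#' @param level Growth-inhibition percentage in (0, 100).
#' @return One-row data frame: `y`, `d_pd`, `d_az`, `D_pd`, `D_az`, `ci`,
#'   `censoring` (one of `"exact"`, `"upper_bound"`, `"unattainable"`).
#' @examples
#' # direct-substitution check: d_PD/D_PD + d_AZ/D_AZ
#' # 0.5/2 + 2/4 = 0.75
#' @export
ci_at_effect <- function(fit_pd, fit_az, fit_combo, design, level) {
  stopifnot(inherits(design, "fixed_ratio_design"))
  for (f in list(fit_pd, fit_az, fit_combo))
    if (!isTRUE(f$converged))
      stop("ci_at_effect requires converged fits for PD, AZ and the combination",
           call. = FALSE)
  r <- design$r
  combo <- dose_at_inhibition(fit_combo, level)
  Dpd   <- dose_at_inhibition(fit_pd, level)
  Daz   <- dose_at_inhibition(fit_az, level)
  row <- data.frame(y = level, d_pd = NA_real_, d_az = NA_real_,
                    D_pd = NA_real_, D_az = NA_real_, ci = NA_real_,
                    censoring = "unattainable", stringsAsFactors = FALSE)
  if (!combo$attainable || combo$censored || !Dpd$attainable ||
      !Daz$attainable)
    return(row)
  d_az <- combo$dose
  d_pd <- r * d_az
  row$d_pd <- d_pd; row$d_az <- d_az
  row$D_pd <- Dpd$dose; row$D_az <- Daz$dose
  row$ci <- d_pd / Dpd$dose + d_az / Daz$dose
  row$censoring <- if (Dpd$censored || Daz$censored) "upper_bound" else "exact"
  row
}

#' Loewe combination-index profile over an effect grid
#'
#' Evaluates [ci_at_effect()] on a grid of effect levels (default IC50 to
#' IC80 in 1-point steps, 31 levels) and summarises the usable points.
#' Points flagged unattainable are kept in the per-point table but excluded
#' from the summary; a profile with fewer than 3 usable points is flagged
#' undefined.
#'
#' @inheritParams ci_at_effect
#' @param grid Numeric vector of effect levels in (0, 100).
#' @return A list of class `ci_profile`: `points` (data frame, one row per
#'   grid level), `summary` (named vector: `median`, `mean`, `q1`, `q3`,
#'   `min`, `max` — all `NA` when undefined), `n_attainable`, `grid`,
#'   `defined` (logical).
#' @export
ci_profile <- function(fit_pd, fit_az, fit_combo, design, grid = 50:80) {
  if (length(grid) == 0) stop("effect grid is empty", call. = FALSE)
  stopifnot(all(grid > 0), all(grid < 100))
  pts <- do.call(rbind, lapply(grid, function(y)
    ci_at_effect(fit_pd, fit_az, fit_combo, design, y)))
  usable <- pts$censoring %in% c("exact", "upper_bound")
  n_att <- sum(usable)
  if (n_att >= 3) {
    ci <- pts$ci[usable]
    q <- stats::quantile(ci, c(0.25, 0.5, 0.75), names = FALSE)
    summ <- c(median = q[2], mean = mean(ci), q1 = q[1], q3 = q[3],
              min = min(ci), max = max(ci))
    defined <- TRUE
  } else {
    summ <- c(median = NA_real_, mean = NA_real_, q1 = NA_real_,
              q3 = NA_real_, min = NA_real_, max = NA_real_)
    defined <- FALSE
  }
  structure(list(points = pts, summary = summ, n_attainable = n_att,
                 grid = grid, defined = defined),
            class = "ci_profile")
}

#' @export
print.ci_profile <- function(x, ...) {
  if (x$defined)
    cat(sprintf("<ci_profile> %d/%d attainable, median CI = %.3f\n",
                x$n_attainable, length(x$grid), x$summary[["median"]]))
  else
    cat(sprintf("<ci_profile> undefined (%d attainable points)\n",
                x$n_attainable))
  invisible(x)
}

#' Classify combination synergy from a summary CI
#'
#' Bands: CI < 0.5 strong synergism; 0.5 <= CI < 0.8 synergism;
#' 0.8 <= CI <= 1.2 additive; CI > 1.2 antagonism. The band edges 0.8 and
#' 1.2, left ambiguous by strict-inequality reading, are assigned to the
#' additive band.
#'
#' @param summary_ci Positive summary combination index (typically the
#'   median CI over the E50-E80 grid).
#' @param bands Numeric length-3 vector of cut points
#'   (strong/synergism/additive upper edges).
#' @return A list of class `synergy_class` with `label` (one of
#'   `"strong_synergism"`, `"synergism"`, `"additive"`, `"antagonism"`) and
#'   `ci`.
#' @examples
#' classify_ci(0.4)$label  # "strong_synergism"
#' classify_ci(1.0)$label  # "additive"
#' @export
classify_ci <- function(summary_ci, bands = c(0.5, 0.8, 1.2)) {
  stopifnot(length(summary_ci) == 1L, is.finite(summary_ci))
  if (summary_ci <= 0)
    stop("summary CI must be strictly positive", call. = FALSE)
  label <- if (summary_ci < bands[1]) "strong_synergism"
  else if (summary_ci < bands[2]) "synergism"
  else if (summary_ci <= bands[3]) "additive"
  else "antagonism"
  structure(list(label = label, ci = summary_ci), class = "synergy_class")
}
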