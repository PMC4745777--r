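#' Dose-response series for one treatment condition
#'
#' Bundles the dose grid and replicate viability measurements for a single
#' cell line / treatment condition. Viability is expressed as percent of the
#' vehicle (DMSO) control; zero-dose control wells are used upstream for
#' normalisation only and are never part of a series.
#'
#' @param condition_id Character label for the condition (e.g. `"H460:PD"`).
#' @param doses Numeric vector of tested concentrations in uM. Strictly
#'   positive; repeated values encode replicates measured at the same dose
#'   unless `viability` is a matrix.
#' @param viability Numeric vector of the same length as `doses`, or a matrix
#'   with one row per dose and one column per replicate. Percent of control,
#'   typically 0-120.
#'
#' @return An object of class `dose_series`: a list with elements
#'   `condition_id`, `data` (a data frame with columns `dose`, `replicate`,
#'   `viability`, sorted by dose then replicate) and `n_replicates`.
#' @examples
#' d <- 10^seq(-2, 2, by = 0.5)
#' v <- 100 / (1 + d)           # top=100, bottom=0, ic50=1, hill=1
#' s <- dose_series("demo", d, v)
#' s$n_replicates
#' @export
dose_series <- function(condition_id, doses, viability) {
  stopifnot(is.character(condition_id), length(condition_id) == 1L)
  if (is.matrix(viability)) {
    if (nrow(viability) != length(doses))
      stop("viability matrix must have one row per dose", call. = FALSE)
    reps <- ncol(viability)
    df <- data.frame(
      dose      = rep(doses, times = reps),
      replicate = rep(seq_len(reps), each = length(doses)),
      viability = as.vector(viability)
    )
  } else {
    if (length(viability) != length(doses))
      stop("doses and viability must have equal length", call. = FALSE)
    df <- data.frame(dose = doses, replicate = NA_integer_,
                     viability = viability)
    df <- df[order(df$dose), , drop = FALSE]
    df$replicate <- stats::ave(df$dose, df$dose, FUN = seq_along)
  }
  if (any(!is.finite(df$dose)) || any(df$dose <= 0))
    stop("doses must be finite and strictly positive", call. = FALSE)
  if (any(!is.finite(df$viability)))
    stop("viability values must be finite", call. = FALSE)
  df <- df[order(df$dose, df$replicate), , drop = FALSE]
  rownames(df) <- NULL
  structure(
    list(condition_id = condition_id, data = df,
         n_replicates = max(table(df$dose))),
    class = "dose_series"
  )
}

#' @export
print.dose_series <- function(x, ...) {
  cat("<dose_series>", x$condition_id, "-",
      length(unique(x$data$dose)), "doses x", x$n_replicates,
      "replicates\n")
  invisible(x)
}

#' Parameter bounds and fitting controls for the 4PL fit
#'
#' The defaults reflect viability data normalised to vehicle control: the
#' upper asymptote is near 100%, the lower asymptote cannot leave \[0, 100\],
#' and the Hill slope is kept in a loosely identifiable range. The IC50
#' search window extends from 1/100 of the lowest tested dose to
#' `extrapolation_limit` times the highest.
#'
#' @param top Length-2 numeric, bounds on the zero-dose asymptote (%).
#' @param bottom Length-2 numeric, bounds on the infinite-dose asymptote (%).
#' @param hill Length-2 numeric, bounds on the (positive) Hill slope.
#' @param extrapolation_limit Multiple of the maximum tested dose beyond
#'   which effect-level doses are censored; also sets the IC50 upper bound.
#' @param n_starts Number of deterministic multi-start initialisations.
#' @return A list of class `fourpl_constraints`.
#' @export
fourpl_constraints <- function(top = c(70, 120), bottom = c(0, 100),
                               hill = c(0.1, 10), extrapolation_limit = 10,
                               n_starts = 5L) {
  stopifnot(top[1] < top[2], bottom[1] < bottom[2], hill[1] > 0,
            hill[1] < hill[2], extrapolation_limit > 1, n_starts >= 1)
  structure(list(top = top, bottom = bottom, hill = hill,
                 extrapolation_limit = extrapolation_limit,
                 n_starts = as.integer(n_starts)),
            class = "fourpl_constraints")
}

## 4PL evaluated on the natural-dose scale via log10 internally.
## viability(d) = bottom + (top - bottom) / (1 + (d / ic50)^hill)
fourpl_curve <- function(dose, top, bottom, ic50, hill) {
  v <- rep(top, length(dose))
  pos <- dose > 0
  v[pos] <- bottom + (top - bottom) /
    (1 + 10^(hill * (log10(dose[pos]) - log10(ic50))))
  v
}

## SSE and analytic gradient in theta = (top, bottom, log10_ic50, hill),
## x = log10(dose)
fourpl_sse <- function(theta, x, v) {
  z <- theta[4] * (x - theta[3])
  s <- 1 / (1 + 10^z)
  r <- theta[2] + (theta[1] - theta[2]) * s - v
  sum(r * r)
}

fourpl_sse_grad <- function(theta, x, v) {
  z <- theta[4] * (x - theta[3])
  s <- 1 / (1 + 10^z)
  r <- theta[2] + (theta[1] - theta[2]) * s - v
  dfdz <- -(theta[1] - theta[2]) * log(10) * s * (1 - s)
  c(2 * sum(r * s),
    2 * sum(r * (1 - s)),
    2 * sum(r * dfdz * (-theta[4])),
    2 * sum(r * dfdz * (x - theta[3])))
}

#' Fit a four-parameter logistic dose-response curve
#'
#' Least-squares fit of
#' \deqn{viability(d) = bottom + (top - bottom) / (1 + (d/IC_{50})^{hill})}
#' on the log10-dose axis. All replicate observations enter the objective
#' individually (no pre-averaging). The optimiser (box-constrained
#' quasi-Newton with an analytic gradient) is restarted from a fixed schedule
#' of initial IC50 positions spread over the tested dose range, with the
#' lowest residual sum of squares winning; ties go to the first start, so the
#' fit is deterministic for a given input.
#'
#' @param series A [dose_series()].
#' @param constraints A [fourpl_constraints()] object.
#' @return An object of class `four_pl_fit`: list with `top`, `bottom`,
#'   `ic50` (uM), `hill`, `dose_range` (min/max tested doses), `converged`,
#'   `rss`, `max_inhibition` (= 100 - bottom), `n_obs`, and the
#'   `extrapolation_limit` carried from `constraints`. `converged` is `FALSE`
#'   when the optimiser reports failure or when IC50 or the Hill slope pin to
#'   their bounds (the asymptotes may legitimately sit on theirs, e.g. a full
#'   kill with `bottom = 0`).
#' @examples
#' d <- 10^seq(-2, 2, by = 0.5)
#' fit <- fit_four_pl(dose_series("demo", d, 100 / (1 + d)))
#' round(c(fit$ic50, fit$hill), 4)
#' @export
fit_four_pl <- function(series, constraints = fourpl_constraints()) {
  stopifnot(inherits(series, "dose_series"),
            inherits(constraints, "fourpl_constraints"))
  df <- series$data
  udose <- sort(unique(df$dose))
  if (length(udose) < 4)
    stop("invalid design: at least 4 distinct doses are required",
         call. = FALSE)
  if (stats::sd(df$viability) == 0)
    stop("degenerate data: viability is constant across all doses",
         call. = FALSE)

  x <- log10(df$dose)
  v <- df$viability
  lq <- log10(min(udose) / 100)
  uq <- log10(max(udose) * constraints$extrapolation_limit)
  lower <- c(constraints$top[1], constraints$bottom[1], lq,
             constraints$hill[1])
  upper <- c(constraints$top[2], constraints$bottom[2], uq,
             constraints$hill[2])

  clamp <- function(val, b) min(max(val, b[1]), b[2])
  top0 <- clamp(mean(v[df$dose == udose[1]]), constraints$top)
  bot0 <- clamp(mean(v[df$dose == udose[length(udose)]]),
                constraints$bottom)
  if (bot0 >= top0) bot0 <- max(constraints$bottom[1], top0 - 10)

  probs <- seq(0.1, 0.9, length.out = constraints$n_starts)
  starts <- lapply(stats::quantile(log10(udose), probs, names = FALSE),
                   function(q) c(top0, bot0, clamp(q, c(lq, uq)), 1))

  fits <- lapply(starts, function(st) tryCatch(
    stats::optim(st, fourpl_sse, gr = fourpl_sse_grad, x = x, v = v,
                 method = "L-BFGS-B", lower = lower, upper = upper,
                 control = list(factr = 1e4, maxit = 500)),
    error = function(e) NULL))
  fits <- Filter(Negate(is.null), fits)
  if (length(fits) == 0)
    stop("degenerate data: optimizer failed from every start", call. = FALSE)
  vals <- vapply(fits, `[[`, numeric(1), "value")
  best_val <- min(vals)
  # several starts often land on the same minimum with different stopping
  # codes; prefer the first cleanly converged one within rounding of it
  clean <- vapply(fits, function(f) f$convergence == 0, logical(1)) &
    vals <= best_val * (1 + 1e-6) + 1e-9
  best <- fits[[if (any(clean)) which(clean)[1] else which.min(vals)]]

  th <- best$par
  tol <- 1e-6
  pinned <- (th[3] - lower[3] < tol) || (upper[3] - th[3] < tol) ||
    (th[4] - lower[4] < tol) || (upper[4] - th[4] < tol)
  structure(
    list(top = th[1], bottom = th[2], ic50 = 10^th[3], hill = th[4],
         dose_range = range(udose),
         converged = (best$convergence == 0) && !pinned && th[2] < th[1],
         rss = best$value,
         max_inhibition = 100 - th[2],
         n_obs = nrow(df),
         extrapolation_limit = constraints$extrapolation_limit,
         condition_id = series$condition_id),
    class = "four_pl_fit"
  )
}

#' @export
print.four_pl_fit <- function(x, ...) {
  cat(sprintf(
    "<four_pl_fit> %s: top=%.1f bottom=%.1f ic50=%.4g uM hill=%.2f %s\n",
    x$condition_id %||% "", x$top, x$bottom, x$ic50, x$hill,
    if (x$converged) "(converged)" else "(NOT converged)"))
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Predict viability from a fitted 4PL curve
#'
#' Forward evaluation of the fitted curve; dose 0 returns `top` by the limit
#' convention. Non-increasing in dose whenever `hill > 0`.
#'
#' @param fit A `four_pl_fit` (or any list with `top`, `bottom`, `ic50`,
#'   `hill`).
#' @param dose Numeric vector of doses in uM, each >= 0.
#' @return Numeric vector of predicted viability (% of control).
#' @export
predict_viability <- function(fit, dose) {
  stopifnot(all(is.finite(dose)), all(dose >= 0))
  fourpl_curve(dose, fit$top, fit$bottom, fit$ic50, fit$hill)
}

#' Dose required to reach a growth-inhibition level (IC_y)
#'
#' Closed-form inversion of the 4PL: the dose at which growth inhibition
#' (100 - viability) equals `level` percent. A level within 2 percentage
#' points of the curve's maximum inhibition (or outside the reachable
#' inhibition range altogether) is reported as unattainable rather than
#' extrapolated, because the inverse dose diverges at the asymptote. Doses
#' beyond `extrapolation_limit` times the highest tested dose are censored at
#' that limit.
#'
#' @param fit A converged `four_pl_fit`.
#' @param level Growth-inhibition percentage in (0, 100) (e.g. 50 for IC50).
#' @param extrapolation_limit Censoring multiple of the maximum tested dose;
#'   defaults to the limit recorded in the fit (10 unless overridden).
#' @param attainability_margin Levels above `max_inhibition - margin` are
#'   unattainable. Default 2 percentage points.
#' @return A list with `dose` (uM, `NA` when unattainable), `censored`
#'   (logical) and `attainable` (logical).
#' @examples
#' fit <- fit_four_pl(dose_series("demo", 10^seq(-2, 2, 0.5),
#'                                100 / (1 + 10^seq(-2, 2, 0.5))))
#' dose_at_inhibition(fit, 80)$dose   # ~4 uM
#' @export
dose_at_inhibition <- function(fit, level,
                               extrapolation_limit = NULL,
                               attainability_margin = 2) {
  stopifnot(length(level) == 1L, is.finite(level), level > 0, level < 100)
  if (!isTRUE(fit$converged))
    stop("dose_at_inhibition requires a converged fit", call. = FALSE)
  lim_mult <- extrapolation_limit %||% fit$extrapolation_limit %||% 10
  v_target <- 100 - level
  out <- list(dose = NA_real_, censored = FALSE, attainable = FALSE)
  if (level > fit$max_inhibition - attainability_margin ||
      v_target >= fit$top)
    return(out)
  d <- fit$ic50 *
    ((fit$top - v_target) / (v_target - fit$bottom))^(1 / fit$hill)
  cap <- lim_mult * fit$dose_range[2]
  if (d > cap) {
    out$dose <- cap
    out$censored <- TRUE
  } else {
    out$dose <- d
  }
  out$attainable <- TRUE
  out
}

#' Classify single-agent sensitivity from an IC50
#'
#' Panel convention: IC50 below 2 uM is sensitive, above 10 uM is resistant
#' (insensitive), anything in between — including the boundary values
#' themselves, read strictly — is intermediate. A censored IC50 (a lower
#' bound produced at the extrapolation limit) is classified resistant.
#'
#' @param ic50 Positive IC50 in uM.
#' @param censored Logical; `TRUE` when `ic50` is a censoring lower bound.
#' @param sensitive_uM,resistant_uM Class thresholds (uM).
#' @return A list of class `sensitivity_class` with `label` (one of
#'   `"sensitive"`, `"intermediate"`, `"resistant"`), `ic50`, `censored`.
#' @examples
#' classify_sensitivity(0.15)$label  # "sensitive"
#' classify_sensitivity(33)$label    # "resistant"
#' @export
classify_sensitivity <- function(ic50, censored = FALSE,
                                 sensitive_uM = 2, resistant_uM = 10) {
  stopifnot(length(ic50) == 1L, is.finite(ic50))
  if (ic50 <= 0) stop("ic50 must be strictly positive", call. = FALSE)
  label <- if (censored || ic50 > resistant_uM) "resistant"
  else if (ic50 < sensitive_uM) "sensitive"
  else "intermediate"
  structure(list(label = label, ic50 = ic50, censored = isTRUE(censored)),
            class = "sensitivity_class")
}
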