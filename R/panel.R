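#' Panel screening configuration
#'
#' Thresholds and numerical settings for [screen_panel()], mirroring the
#' published conventions: sensitivity thresholds of 2 uM (sensitive) and
#' 10 uM (resistant), synergy bands at CI 0.5 / 0.8 / 1.2, and the CI
#' effect grid spanning 50-80% growth inhibition.
#'
#' @param sensitive_uM,resistant_uM Sensitivity thresholds (uM).
#' @param ci_bands Length-3 CI cut points (strong synergism / synergism /
#'   additive upper edges).
#' @param effect_grid Effect levels (% inhibition) for CI profiles.
#' @param extrapolation_limit Censoring multiple of the top tested dose.
#' @param constraints A [fourpl_constraints()]; its extrapolation limit is
#'   kept in sync with `extrapolation_limit`.
#' @return A list of class `screen_config`.
#' @export
screen_config <- function(sensitive_uM = 2, resistant_uM = 10,
                          ci_bands = c(0.5, 0.8, 1.2),
                          effect_grid = 50:80,
                          extrapolation_limit = 10,
                          constraints = fourpl_constraints(
                            extrapolation_limit = extrapolation_limit)) {
  stopifnot(sensitive_uM < resistant_uM, length(ci_bands) == 3,
            all(diff(ci_bands) > 0))
  structure(list(sensitive_uM = sensitive_uM, resistant_uM = resistant_uM,
                 ci_bands = ci_bands, effect_grid = effect_grid,
                 extrapolation_limit = extrapolation_limit,
                 constraints = constraints),
            class = "screen_config")
}

## IC50 (50% inhibition) on the reporting axis, with censoring bookkeeping.
## For combinations the reporting axis is total drug (1+r) * d_AZ.
reported_ic50 <- function(fit, r = NA_real_) {
  if (!isTRUE(fit$converged))
    return(list(ic50 = NA_real_, censored = TRUE))
  inv <- dose_at_inhibition(fit, 50)
  scale <- if (is.na(r)) 1 else 1 + r
  list(ic50 = if (inv$attainable) inv$dose * scale else NA_real_,
       censored = !inv$attainable || inv$censored)
}

sensitivity_label <- function(ic50, censored, cfg) {
  if (is.na(ic50)) return("resistant")   # cannot reach 50% inhibition
  classify_sensitivity(ic50, censored, cfg$sensitive_uM,
                       cfg$resistant_uM)$label
}

#' Screen a full dose-response panel
#'
#' Orchestrates the complete analysis over a long-format table of viability
#' measurements: fits a 4PL curve to every cell line x condition (x ratio)
#' series, classifies single-agent and combination sensitivity from the
#' fitted IC50 (combination IC50 reported as total drug concentration
#' `(1+r) * d_AZ`), computes a Loewe CI profile over the effect grid for
#' every combination, classifies synergy from the median CI, and tallies
#' panel-level counts. Lines whose required fits fail are reported in an
#' exclusions table, never silently dropped. Input row order is irrelevant:
#' the table is sorted internally, so identical data give identical
#' results.
#'
#' @param data Data frame with columns `cell_line`, `condition` (`"PD"`,
#'   `"AZ"` or `"COMBO"`), `ratio` (`NA` for single agents; numeric or
#'   `"0.25:1"`-style for combinations), `dose_uM`, `replicate`,
#'   `viability_pct`.
#' @param config A [screen_config()].
#' @return An object of class `panel_result`: list with
#'   \describe{
#'     \item{fits}{per-series fit table (parameters, convergence, reported
#'       IC50 and sensitivity class)}
#'     \item{ci}{per line x ratio CI summary table with synergy class}
#'     \item{profiles}{named list of [ci_profile()] objects
#'       (`"line@ratio"`)}
#'     \item{counts}{sensitivity counts and integer percentages per
#'       condition}
#'     \item{synergy_counts}{synergy-class counts per ratio}
#'     \item{optimal_ratio}{ratio chosen by [select_optimal_ratio()], `NA`
#'       if undecidable}
#'     \item{exclusions}{table of skipped series and the reason}
#'     \item{n_lines, ratio_set, config}{bookkeeping}
#'   }
#' @export
screen_panel <- function(data, config = screen_config()) {
  stopifnot(inherits(config, "screen_config"))
  req <- c("cell_line", "condition", "ratio", "dose_uM", "replicate",
           "viability_pct")
  missing_cols <- setdiff(req, names(data))
  if (length(missing_cols))
    stop("input is missing columns: ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  data$ratio <- vapply(data$ratio, function(x)
    if (is.na(x) || identical(x, "")) NA_real_ else parse_ratio(x),
    numeric(1))
  data <- data[order(data$cell_line, data$condition, data$ratio,
                     data$dose_uM, data$replicate, data$viability_pct), ]

  lines <- sort(unique(data$cell_line))
  ratio_set <- sort(unique(data$ratio[data$condition == "COMBO"]))

  fit_rows <- list(); ci_rows <- list(); excl <- list()
  profiles <- list()
  add_excl <- function(line, cond, ratio, msg)
    excl[[length(excl) + 1L]] <<- data.frame(
      cell_line = line, condition = cond, ratio = ratio, reason = msg,
      stringsAsFactors = FALSE)

  fit_one <- function(sub, id) {
    s <- dose_series(id, sub$dose_uM, sub$viability_pct)
    fit_four_pl(s, config$constraints)
  }

  for (ln in lines) {
    dl <- data[data$cell_line == ln, ]
    sfit <- list()
    for (cond in c("PD", "AZ")) {
      sub <- dl[dl$condition == cond, ]
      if (nrow(sub) == 0) {
        add_excl(ln, cond, NA_real_, "missing single-agent series")
        next
      }
      f <- tryCatch(fit_one(sub, paste0(ln, ":", cond)),
                    error = function(e) conditionMessage(e))
      if (is.character(f)) { add_excl(ln, cond, NA_real_, f); next }
      sfit[[cond]] <- f
      rep50 <- reported_ic50(f)
      fit_rows[[length(fit_rows) + 1L]] <- data.frame(
        cell_line = ln, condition = cond, ratio = NA_real_,
        top = f$top, bottom = f$bottom, ic50_fit_uM = f$ic50,
        hill = f$hill, converged = f$converged, rss = f$rss,
        ic50_uM = rep50$ic50, censored = rep50$censored,
        ic50_class = if (f$converged)
          sensitivity_label(rep50$ic50, rep50$censored, config)
        else NA_character_,
        stringsAsFactors = FALSE)
    }
    for (r in ratio_set) {
      sub <- dl[dl$condition == "COMBO" & !is.na(dl$ratio) &
                  dl$ratio == r, ]
      if (nrow(sub) == 0) {
        add_excl(ln, "COMBO", r, "no combination series at this ratio")
        next
      }
      if (is.null(sfit$PD) || is.null(sfit$AZ)) {
        add_excl(ln, "COMBO", r,
                 "single-agent fit unavailable for CI analysis")
        next
      }
      f <- tryCatch(fit_one(sub, paste0(ln, ":COMBO:", format(r))),
                    error = function(e) conditionMessage(e))
      if (is.character(f)) { add_excl(ln, "COMBO", r, f); next }
      rep50 <- reported_ic50(f, r)
      fit_rows[[length(fit_rows) + 1L]] <- data.frame(
        cell_line = ln, condition = "COMBO", ratio = r,
        top = f$top, bottom = f$bottom, ic50_fit_uM = f$ic50,
        hill = f$hill, converged = f$converged, rss = f$rss,
        ic50_uM = rep50$ic50, censored = rep50$censored,
        ic50_class = if (f$converged)
          sensitivity_label(rep50$ic50, rep50$censored, config)
        else NA_character_,
        stringsAsFactors = FALSE)
      if (!f$converged || !sfit$PD$converged || !sfit$AZ$converged) {
        add_excl(ln, "COMBO", r, "non-converged fit, CI not computed")
        next
      }
      prof <- ci_profile(sfit$PD, sfit$AZ, f, fixed_ratio_design(r),
                         config$effect_grid)
      profiles[[paste0(ln, "@", format(r))]] <- prof
      ci_rows[[length(ci_rows) + 1L]] <- data.frame(
        cell_line = ln, ratio = r,
        median_ci = prof$summary[["median"]],
        mean_ci = prof$summary[["mean"]],
        q1 = prof$summary[["q1"]], q3 = prof$summary[["q3"]],
        n_attainable = prof$n_attainable, defined = prof$defined,
        synergy_class = if (prof$defined)
          classify_ci(prof$summary[["median"]], config$ci_bands)$label
        else NA_character_,
        stringsAsFactors = FALSE)
      if (!prof$defined)
        add_excl(ln, "COMBO", r,
                 "CI profile undefined (fewer than 3 attainable points)")
    }
  }

  fits <- if (length(fit_rows)) do.call(rbind, fit_rows) else NULL
  ci <- if (length(ci_rows)) do.call(rbind, ci_rows) else NULL
  res <- structure(
    list(fits = fits, ci = ci, profiles = profiles,
         counts = NULL, synergy_counts = NULL, optimal_ratio = NA_real_,
         exclusions = if (length(excl)) do.call(rbind, excl) else
           data.frame(cell_line = character(), condition = character(),
                      ratio = numeric(), reason = character()),
         n_lines = length(lines), ratio_set = ratio_set, config = config),
    class = "panel_result")
  res$counts <- build_counts(res)
  res$synergy_counts <- build_synergy_counts(res)
  res$optimal_ratio <- tryCatch(select_optimal_ratio(res),
                                error = function(e) NA_real_)
  res
}

## round-half-up integer percent, matching "8 out of 28 (29%)"
pct_round <- function(count, n) as.integer(floor(100 * count / n + 0.5))

condition_key <- function(condition, ratio)
  ifelse(is.na(ratio), condition, paste0(condition, "@", format(ratio)))

build_counts <- function(panel) {
  f <- panel$fits
  if (is.null(f)) return(NULL)
  f <- f[!is.na(f$ic50_class), ]
  key <- condition_key(f$condition, f$ratio)
  out <- lapply(unique(key), function(k) {
    cls <- f$ic50_class[key == k]
    n <- length(cls)
    data.frame(condition = k, n = n,
               n_sensitive = sum(cls == "sensitive"),
               n_intermediate = sum(cls == "intermediate"),
               n_resistant = sum(cls == "resistant"),
               pct_sensitive = pct_round(sum(cls == "sensitive"), n),
               pct_intermediate = pct_round(sum(cls == "intermediate"), n),
               pct_resistant = pct_round(sum(cls == "resistant"), n),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

build_synergy_counts <- function(panel) {
  ci <- panel$ci
  if (is.null(ci)) return(NULL)
  ci <- ci[!is.na(ci$synergy_class), ]
  out <- lapply(sort(unique(ci$ratio)), function(r) {
    cls <- ci$synergy_class[ci$ratio == r]
    data.frame(ratio = r, n = length(cls),
               n_strong = sum(cls == "strong_synergism"),
               n_synergistic = sum(cls %in%
                                     c("strong_synergism", "synergism")),
               n_additive = sum(cls == "additive"),
               n_antagonistic = sum(cls == "antagonism"),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' @export
print.panel_result <- function(x, ...) {
  cat(sprintf("<panel_result> %d lines, ratios: %s\n", x$n_lines,
              paste(format(x$ratio_set), collapse = ", ")))
  if (!is.null(x$counts)) { cat("sensitivity counts:\n"); print(x$counts) }
  if (!is.null(x$synergy_counts)) {
    cat("synergy counts:\n"); print(x$synergy_counts)
  }
  cat("optimal ratio:", format(x$optimal_ratio), "\n")
  if (nrow(x$exclusions))
    cat(nrow(x$exclusions), "exclusion(s); see $exclusions\n")
  invisible(x)
}

#' Sensitivity counts and integer percentages for one condition
#'
#' @param panel A `panel_result`.
#' @param condition Condition key: `"PD"`, `"AZ"`, or `"COMBO@<ratio>"`
#'   (e.g. `"COMBO@0.25"`).
#' @return One-row data frame of counts and round-half-up integer
#'   percentages.
#' @export
sensitivity_summary <- function(panel, condition) {
  stopifnot(inherits(panel, "panel_result"))
  row <- panel$counts[panel$counts$condition == condition, ]
  if (nrow(row) == 0)
    stop("unknown condition: ", condition, call. = FALSE)
  row
}

#' Select the optimal combination ratio
#'
#' The optimal ratio is the one with the most lines classified synergistic
#' or stronger (median CI below the synergism band edge). Ties are broken
#' by the lower median of per-line median CIs, then by the smaller ratio
#' value.
#'
#' @param panel A `panel_result` with at least one ratio carrying valid CI
#'   summaries.
#' @return The selected ratio (numeric).
#' @export
select_optimal_ratio <- function(panel) {
  stopifnot(inherits(panel, "panel_result"))
  ci <- panel$ci
  if (is.null(ci)) stop("no CI summaries available", call. = FALSE)
  ci <- ci[!is.na(ci$median_ci), ]
  if (nrow(ci) == 0)
    stop("no ratio with valid CI summaries", call. = FALSE)
  ratios <- sort(unique(ci$ratio))
  score <- data.frame(
    ratio = ratios,
    n_syn = vapply(ratios, function(r)
      sum(ci$synergy_class[ci$ratio == r] %in%
            c("strong_synergism", "synergism")), integer(1)),
    med = vapply(ratios, function(r)
      stats::median(ci$median_ci[ci$ratio == r]), numeric(1)))
  score <- score[order(-score$n_syn, score$med, score$ratio), ]
  score$ratio[1]
}

#' Read a long-format dose-response CSV
#'
#' Expects columns `cell_line`, `condition`, `ratio`, `dose_uM`,
#' `replicate`, `viability_pct` (extra columns pass through). Blank or
#' missing ratios are treated as single-agent rows; `"0.25:1"`-style
#' ratios are parsed to numbers.
#'
#' @param path CSV file path.
#' @return Data frame ready for [screen_panel()].
#' @export
read_panel_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!"ratio" %in% names(df)) df$ratio <- NA_real_
  df$ratio <- vapply(df$ratio, function(x) {
    x <- trimws(as.character(x))
    if (is.na(x) || x %in% c("", "NA")) NA_real_ else parse_ratio(x)
  }, numeric(1))
  df
}

#' Write panel screening results to CSV
#'
#' Emits the per-series fit table and the per-line CI summary table.
#'
#' @param panel A `panel_result`.
#' @param fits_path,ci_path Output file paths (either may be `NULL` to
#'   skip).
#' @return Invisibly, the written paths.
#' @export
write_panel_results <- function(panel, fits_path = NULL, ci_path = NULL) {
  stopifnot(inherits(panel, "panel_result"))
  if (!is.null(fits_path))
    utils::write.csv(format_num_df(panel$fits), fits_path,
                     row.names = FALSE, quote = FALSE)
  if (!is.null(ci_path) && !is.null(panel$ci))
    utils::write.csv(format_num_df(panel$ci), ci_path,
                     row.names = FALSE, quote = FALSE)
  invisible(c(fits_path, ci_path))
}
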