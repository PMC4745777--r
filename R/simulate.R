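#' Synthetic panel specification
#'
#' Describes a simulated cell-line panel with known ground truth. Defaults
#' emulate a 28-line non-small-cell lung cancer screen of a MEK inhibitor
#' ("PD") and a SRC inhibitor ("AZ"): per-line single-agent IC50s are drawn
#' log-uniformly over ranges spanning the published spreads (PD roughly
#' 0.03-150 uM, i.e. from below 50 nM to above 100 uM; AZ 0.15-33 uM),
#' viability carries 5% multiplicative lognormal noise, and each condition
#' is measured in three independent replicates. Combinations are laid down
#' at fixed PD:AZ ratios with a chosen constant true Loewe index kappa per
#' line.
#'
#' @param n_lines Number of cell lines.
#' @param ic50_log10_pd,ic50_log10_az Length-2 log10-uM ranges the
#'   single-agent IC50s are drawn from (uniform in log10).
#' @param hill_range Length-2 range for Hill slopes (uniform).
#' @param bottom_range Length-2 range for the lower asymptote (%); kept
#'   below 20 so the E50-E80 grid stays attainable on true curves.
#' @param top Upper asymptote (%), fixed at 100 (data are normalised to
#'   control).
#' @param dose_grid Single-agent dose grid (uM); default 9-point half-log
#'   series 0.01-100 uM.
#' @param combo_dose_grid AZ-component dose grid for combinations; default
#'   9-point half-log series 0.004-40 uM, bracketing the combination IC50s
#'   expected at a 0.25:1 ratio.
#' @param ratio_set PD:AZ ratios to simulate (numeric or "4:1"-style).
#' @param kappa Per-line true Loewe index: a single value recycled, a
#'   vector of length `n_lines`, or a function `function(n)` returning one
#'   draw per line. Default draws log-uniformly in \[0.3, 1.5\].
#' @param noise_cv Multiplicative coefficient of variation of the lognormal
#'   well noise.
#' @param n_replicates Independent replicates per condition (default 3).
#' @param seed Master seed; per-line/per-condition substreams are derived
#'   from it by a fixed hash so adding a line does not perturb the others.
#' @return A list of class `synthetic_panel_spec`.
#' @export
synthetic_panel_spec <- function(n_lines = 28,
                                 ic50_log10_pd = c(log10(0.03), log10(150)),
                                 ic50_log10_az = c(log10(0.15), log10(33)),
                                 hill_range = c(0.8, 1.5),
                                 bottom_range = c(0, 10),
                                 top = 100,
                                 dose_grid = 10^seq(-2, 2, by = 0.5),
                                 combo_dose_grid = 0.004 * 10^seq(0, 4, by = 0.5),
                                 ratio_set = c(4, 1, 0.25),
                                 kappa = function(n) 10^stats::runif(n, log10(0.3), log10(1.5)),
                                 noise_cv = 0.05,
                                 n_replicates = 3L,
                                 seed = 1L) {
  stopifnot(n_lines >= 1, diff(ic50_log10_pd) > 0, diff(ic50_log10_az) > 0,
            diff(hill_range) > 0, diff(bottom_range) >= 0,
            all(diff(dose_grid) > 0), all(diff(combo_dose_grid) > 0),
            noise_cv >= 0, n_replicates >= 1)
  ratio_set <- vapply(ratio_set, parse_ratio, numeric(1))
  structure(list(n_lines = as.integer(n_lines),
                 ic50_log10_pd = ic50_log10_pd,
                 ic50_log10_az = ic50_log10_az,
                 hill_range = hill_range, bottom_range = bottom_range,
                 top = top, dose_grid = dose_grid,
                 combo_dose_grid = combo_dose_grid, ratio_set = ratio_set,
                 kappa = kappa, noise_cv = noise_cv,
                 n_replicates = as.integer(n_replicates),
                 seed = as.integer(seed)),
            class = "synthetic_panel_spec")
}

## Deterministic substream seed: polynomial string hash folded with the
## master seed, modulo 2^31 - 1 (keeps set.seed() in 32-bit range).
derive_seed <- function(master, label) {
  m <- 2147483647
  h <- 0
  for (c in utf8ToInt(label)) h <- (h * 31 + c) %% m
  as.integer(((master %% m) * 48271 + h) %% m)
}

## mean-1 multiplicative lognormal noise with coefficient of variation cv
lognormal_noise <- function(n, cv) {
  if (cv == 0) return(rep(1, n))
  sdlog <- sqrt(log(1 + cv^2))
  stats::rlnorm(n, meanlog = -sdlog^2 / 2, sdlog = sdlog)
}

#' Simulate a single-agent dose-response series
#'
#' Evaluates a true 4PL curve on the dose grid and multiplies each well by
#' independent mean-one lognormal noise with the given coefficient of
#' variation (viability is a positive ratio measure, so the noise is
#' multiplicative). Deterministic for a fixed seed.
#'
#' @param truth List with `top`, `bottom`, `ic50`, `hill`.
#' @param dose_grid Strictly increasing positive doses (uM).
#' @param noise_cv Coefficient of variation (>= 0).
#' @param n_replicates Replicates per dose.
#' @param seed Integer seed.
#' @param condition_id Label for the resulting series.
#' @return A [dose_series()].
#' @export
simulate_single_agent <- function(truth, dose_grid, noise_cv = 0.05,
                                  n_replicates = 3L, seed = 1L,
                                  condition_id = "sim") {
  if (noise_cv < 0) stop("noise_cv must be non-negative", call. = FALSE)
  stopifnot(all(dose_grid > 0), truth$ic50 > 0, truth$hill > 0,
            truth$bottom < truth$top)
  mu <- fourpl_curve(dose_grid, truth$top, truth$bottom, truth$ic50,
                     truth$hill)
  nd <- length(dose_grid)
  withr_seed(seed)
  vmat <- matrix(rep(mu, n_replicates) *
                   lognormal_noise(nd * n_replicates, noise_cv),
                 nrow = nd, ncol = n_replicates)
  dose_series(condition_id, dose_grid, vmat)
}

## set.seed without leaking RNG state changes into the caller's stream
withr_seed <- function(seed) {
  set.seed(seed, kind = "Mersenne-Twister", normal.kind = "Inversion")
}

## True single-agent dose at inhibition y (closed form, no censoring)
true_inverse <- function(truth, y) {
  v <- 100 - y
  truth$ic50 * ((truth$top - v) / (v - truth$bottom))^(1 / truth$hill)
}

#' True combination effect curve under a constant Loewe index
#'
#' Under the constant-index construction, the AZ-component dose that
#' achieves inhibition `y` at fixed ratio `r` is
#' \deqn{d_{AZ}(y) = \kappa / ( r / D_{PD}(y) + 1 / D_{AZ}(y) ),}
#' the unique dose solving the Loewe equation
#' `r*d_AZ/D_PD + d_AZ/D_AZ = kappa`. This helper inverts that monotone
#' dose-effect map numerically at given AZ-component doses.
#'
#' @param truth_pd,truth_az True 4PL parameter lists.
#' @param r PD:AZ ratio.
#' @param kappa Constant true Loewe index (> 0).
#' @param dose_az AZ-component doses (uM) at which to evaluate the effect.
#' @return Growth-inhibition percentages at `dose_az`.
#' @export
true_combo_effect <- function(truth_pd, truth_az, r, kappa, dose_az) {
  y_max <- min(100 - truth_pd$bottom, 100 - truth_az$bottom) - 1e-6
  eps <- 1e-9
  d_of_y <- function(y)
    kappa / (r / true_inverse(truth_pd, y) + 1 / true_inverse(truth_az, y))
  vapply(dose_az, function(d) {
    if (d <= 0) return(0)
    f <- function(y) log(d_of_y(y)) - log(d)
    lo <- eps; hi <- y_max
    if (f(lo) >= 0) return(0)          # dose below the curve's range
    if (f(hi) <= 0) return(y_max)      # dose saturates the reachable effect
    stats::uniroot(f, c(lo, hi), tol = 1e-12)$root
  }, numeric(1))
}

#' Simulate a fixed-ratio combination series with known Loewe index
#'
#' Constructs the combination dose-response curve that has a constant true
#' Loewe combination index `kappa` at every effect level (see
#' [true_combo_effect()]), samples it on the AZ-component dose grid, and
#' adds multiplicative lognormal noise per well. A pipeline that fits this
#' series and computes CI over any attainable effect grid should recover
#' `kappa`.
#'
#' @param truth_pd,truth_az True single-agent 4PL parameter lists; both
#'   curves must reach more than 80% inhibition so the E50-E80 grid is
#'   attainable.
#' @param design A [fixed_ratio_design()] (or a ratio accepted by
#'   [parse_ratio()]).
#' @param kappa Constant true Loewe index (> 0).
#' @param dose_grid AZ-component dose grid (uM).
#' @inheritParams simulate_single_agent
#' @return A [dose_series()] on the AZ-component dose axis, with the true
#'   effect curve attached as attribute `"truth"`.
#' @export
simulate_combination <- function(truth_pd, truth_az, design, kappa,
                                 dose_grid, noise_cv = 0.05,
                                 n_replicates = 3L, seed = 1L,
                                 condition_id = "sim_combo") {
  if (!inherits(design, "fixed_ratio_design"))
    design <- fixed_ratio_design(design)
  if (kappa <= 0) stop("kappa must be strictly positive", call. = FALSE)
  if (noise_cv < 0) stop("noise_cv must be non-negative", call. = FALSE)
  if (100 - truth_pd$bottom <= 80 || 100 - truth_az$bottom <= 80)
    stop("both single-agent curves must reach >80% inhibition",
         call. = FALSE)
  y <- true_combo_effect(truth_pd, truth_az, design$r, kappa, dose_grid)
  y_max <- min(100 - truth_pd$bottom, 100 - truth_az$bottom) - 1e-6
  if (all(y <= 0) || all(y >= y_max - 1e-6))
    stop("unusable design: kappa places the combination curve entirely ",
         "outside (below) the dose grid", call. = FALSE)
  mu <- 100 - y
  nd <- length(dose_grid)
  withr_seed(seed)
  vmat <- matrix(rep(mu, n_replicates) *
                   lognormal_noise(nd * n_replicates, noise_cv),
                 nrow = nd, ncol = n_replicates)
  out <- dose_series(condition_id, dose_grid, vmat)
  attr(out, "truth") <- list(kappa = kappa, r = design$r,
                             effect = y, dose_az = dose_grid)
  out
}

#' Simulate a full panel with ground truth
#'
#' Draws per-line single-agent 4PL parameters from the spec's ranges
#' (IC50 uniform in log10), generates single-agent and fixed-ratio
#' combination series for every line, and returns both the long-format
#' data table consumed by [screen_panel()] and a ground-truth table.
#' Per-line, per-condition random substreams are derived from the master
#' seed by a fixed hash, so results are reproducible and adding a line
#' leaves the others untouched.
#'
#' @param spec A [synthetic_panel_spec()].
#' @return A list of class `synthetic_panel` with `data` (data frame:
#'   `cell_line`, `condition`, `ratio`, `dose_uM`, `replicate`,
#'   `viability_pct`) and `truth` (data frame of per-line true parameters
#'   and kappas).
#' @export
simulate_panel <- function(spec) {
  stopifnot(inherits(spec, "synthetic_panel_spec"))
  n <- spec$n_lines
  withr_seed(derive_seed(spec$seed, "panel-parameters"))
  lines <- sprintf("SIM%02d", seq_len(n))
  pd_ic50 <- 10^stats::runif(n, spec$ic50_log10_pd[1], spec$ic50_log10_pd[2])
  az_ic50 <- 10^stats::runif(n, spec$ic50_log10_az[1], spec$ic50_log10_az[2])
  pd_hill <- stats::runif(n, spec$hill_range[1], spec$hill_range[2])
  az_hill <- stats::runif(n, spec$hill_range[1], spec$hill_range[2])
  pd_bot  <- stats::runif(n, spec$bottom_range[1], spec$bottom_range[2])
  az_bot  <- stats::runif(n, spec$bottom_range[1], spec$bottom_range[2])
  kap <- spec$kappa
  kmat <- if (is.function(kap)) {
    matrix(rep(kap(n), length(spec$ratio_set)), nrow = n)
  } else {
    matrix(rep_len(kap, n), nrow = n, ncol = length(spec$ratio_set))
  }

  rows <- vector("list", n * (2 + length(spec$ratio_set)))
  k <- 0L
  series_rows <- function(series, line, condition, ratio) {
    df <- series$data
    data.frame(cell_line = line, condition = condition, ratio = ratio,
               dose_uM = df$dose, replicate = df$replicate,
               viability_pct = df$viability, stringsAsFactors = FALSE)
  }
  for (i in seq_len(n)) {
    tpd <- list(top = spec$top, bottom = pd_bot[i], ic50 = pd_ic50[i],
                hill = pd_hill[i])
    taz <- list(top = spec$top, bottom = az_bot[i], ic50 = az_ic50[i],
                hill = az_hill[i])
    s_pd <- simulate_single_agent(
      tpd, spec$dose_grid, spec$noise_cv, spec$n_replicates,
      derive_seed(spec$seed, paste0(lines[i], ":PD")),
      paste0(lines[i], ":PD"))
    s_az <- simulate_single_agent(
      taz, spec$dose_grid, spec$noise_cv, spec$n_replicates,
      derive_seed(spec$seed, paste0(lines[i], ":AZ")),
      paste0(lines[i], ":AZ"))
    rows[[k <- k + 1L]] <- series_rows(s_pd, lines[i], "PD", NA_real_)
    rows[[k <- k + 1L]] <- series_rows(s_az, lines[i], "AZ", NA_real_)
    for (j in seq_along(spec$ratio_set)) {
      r <- spec$ratio_set[j]
      lbl <- paste0(lines[i], ":COMBO:", format(r))
      s_co <- simulate_combination(
        tpd, taz, fixed_ratio_design(r), kmat[i, j],
        spec$combo_dose_grid, spec$noise_cv, spec$n_replicates,
        derive_seed(spec$seed, lbl), lbl)
      rows[[k <- k + 1L]] <- series_rows(s_co, lines[i], "COMBO", r)
    }
  }
  truth <- data.frame(
    cell_line = lines,
    pd_ic50 = pd_ic50, pd_hill = pd_hill, pd_bottom = pd_bot,
    az_ic50 = az_ic50, az_hill = az_hill, az_bottom = az_bot,
    stringsAsFactors = FALSE)
  for (j in seq_along(spec$ratio_set))
    truth[[paste0("kappa_r", format(spec$ratio_set[j]))]] <- kmat[, j]
  structure(list(data = do.call(rbind, rows), truth = truth, spec = spec),
            class = "synthetic_panel")
}

#' @export
print.synthetic_panel <- function(x, ...) {
  cat(sprintf("<synthetic_panel> %d lines, %d ratios, %d rows\n",
              x$spec$n_lines, length(x$spec$ratio_set), nrow(x$data)))
  invisible(x)
}

#' Write a simulated panel to CSV
#'
#' Emits the long-format data table and the ground-truth table as plain
#' CSV, byte-identical for identical spec and seed.
#'
#' @param panel A `synthetic_panel` from [simulate_panel()].
#' @param data_path,truth_path Output file paths.
#' @return Invisibly, the two paths.
#' @export
write_panel_csv <- function(panel, data_path, truth_path) {
  stopifnot(inherits(panel, "synthetic_panel"))
  utils::write.csv(format_num_df(panel$data), data_path, row.names = FALSE,
                   quote = FALSE)
  utils::write.csv(format_num_df(panel$truth), truth_path,
                   row.names = FALSE, quote = FALSE)
  invisible(c(data_path, truth_path))
}

## locale-independent numeric formatting for reproducible CSV output
format_num_df <- function(df) {
  for (nm in names(df))
    if (is.numeric(df[[nm]]) && !is.integer(df[[nm]]))
      df[[nm]] <- vapply(df[[nm]], function(v)
        if (is.na(v)) "NA" else sprintf("%.15g", v), character(1))
  df
}
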