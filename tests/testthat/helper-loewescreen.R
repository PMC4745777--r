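# Shared fixtures and independent oracles. Everything here is generated in
# code; no data files.

HALF_LOG_GRID <- 10^seq(-2, 2, by = 0.5)   # 9-point, 0.01-100 uM
COMBO_GRID <- 0.004 * 10^seq(0, 4, by = 0.5)
WIDE_COMBO_GRID <- 0.004 * 10^seq(0, 5, by = 0.5)  # for resistant lines

exact_series <- function(truth, doses = HALF_LOG_GRID, id = "exact") {
  dose_series(id, doses,
              fourpl_truth(doses, truth))
}

fourpl_truth <- function(dose, p)
  p$bottom + (p$top - p$bottom) / (1 + (dose / p$ic50)^p$hill)

exact_fit <- function(truth, doses = HALF_LOG_GRID, id = "exact")
  fit_four_pl(exact_series(truth, doses, id))

rand_truth <- function(top = 100, bottom_max = 0,
                       logic50 = c(-1, 1), hill = c(0.8, 1.5)) {
  list(top = top,
       bottom = if (bottom_max > 0) runif(1, 0, bottom_max) else 0,
       ic50 = 10^runif(1, logic50[1], logic50[2]),
       hill = runif(1, hill[1], hill[2]))
}

# Independent oracle: dense grid search over (log10 IC50, Hill) at known
# asymptotes, minimizing SSE. Vectorized over the IC50 grid per Hill value.
grid_fit_oracle <- function(doses, viability, top, bottom,
                            logic50_grid = seq(-2.5, 2.5, by = 0.005),
                            hill_grid = seq(0.2, 4, by = 0.005)) {
  x <- log10(doses)
  best <- c(sse = Inf, logic50 = NA, hill = NA)
  for (h in hill_grid) {
    # rows: logic50 grid, cols: observations
    z <- h * outer(-logic50_grid, x, `+`)
    pred <- bottom + (top - bottom) / (1 + 10^z)
    sse <- rowSums((pred - rep(viability, each = length(logic50_grid)))^2)
    i <- which.min(sse)
    if (sse[i] < best["sse"])
      best <- c(sse = sse[i], logic50 = logic50_grid[i], hill = h)
  }
  best
}

brute_inv <- function(p, y) {
  v <- 100 - y
  p$ic50 * ((p$top - v) / (v - p$bottom))^(1 / p$hill)
}

# Brute-force oracle for the constant-index combination dose: solve the
# Loewe equation r*d/D_PD + d/D_AZ = kappa by root finding.
brute_combo_dose <- function(truth_pd, truth_az, r, kappa, y) {
  inv <- function(p, y) {
    v <- 100 - y
    p$ic50 * ((p$top - v) / (v - p$bottom))^(1 / p$hill)
  }
  Dpd <- inv(truth_pd, y); Daz <- inv(truth_az, y)
  uniroot(function(d) r * d / Dpd + d / Daz - kappa,
          c(1e-12, 1e9), tol = 1e-14)$root
}

# One sham or constant-index pipeline run: simulate PD, AZ and the
# combination, fit all three, return the CI profile.
pipeline_ci <- function(truth_pd, truth_az, r, kappa, noise_cv, seed,
                        n_replicates = 3L,
                        dose_grid = HALF_LOG_GRID,
                        combo_grid = COMBO_GRID) {
  s_pd <- simulate_single_agent(truth_pd, dose_grid, noise_cv,
                                n_replicates, seed, "PD")
  s_az <- simulate_single_agent(truth_az, dose_grid, noise_cv,
                                n_replicates, seed + 1L, "AZ")
  s_co <- simulate_combination(truth_pd, truth_az, r, kappa, combo_grid,
                               noise_cv, n_replicates, seed + 2L, "CO")
  ci_profile(fit_four_pl(s_pd), fit_four_pl(s_az), fit_four_pl(s_co),
             fixed_ratio_design(r))
}

# Long-format rows for hand-built panels
panel_rows <- function(line, condition, ratio, series) {
  df <- series$data
  data.frame(cell_line = line, condition = condition, ratio = ratio,
             dose_uM = df$dose, replicate = df$replicate,
             viability_pct = df$viability, stringsAsFactors = FALSE)
}
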