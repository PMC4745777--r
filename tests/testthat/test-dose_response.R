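test_that("noise-free 4PL fits recover generating parameters to 0.1%", {
  truth <- list(top = 100, bottom = 0, ic50 = 1, hill = 1)
  fit <- exact_fit(truth)
  expect_true(fit$converged)
  expect_lt(abs(fit$ic50 - 1), 1e-3)
  expect_lt(abs(fit$hill - 1), 1e-3)
  expect_lt(abs(fit$top - 100), 0.1)
  expect_lt(abs(fit$bottom - 0), 0.1)

  set.seed(11)
  for (i in 1:10) {
    truth <- rand_truth(bottom_max = 15)
    fit <- exact_fit(truth)
    expect_true(fit$converged)
    expect_lt(abs(fit$ic50 / truth$ic50 - 1), 1e-3)
    expect_lt(abs(fit$hill / truth$hill - 1), 1e-3)
  }
})

test_that("noisy fit agrees with the dense grid-search oracle", {
  truth <- list(top = 100, bottom = 0, ic50 = 1, hill = 1)
  s <- simulate_single_agent(truth, HALF_LOG_GRID, noise_cv = 0.05,
                             n_replicates = 3, seed = 7)
  fit <- fit_four_pl(s)
  expect_true(fit$converged)
  expect_lt(abs(log10(fit$ic50)), 0.1)   # within 0.1 of log10(1) = 0

  # oracle holds the asymptotes at the fitted values so both methods
  # minimize SSE over the same (log IC50, Hill) slice
  orc <- grid_fit_oracle(s$data$dose, s$data$viability,
                         top = fit$top, bottom = fit$bottom)
  expect_lt(abs(log10(fit$ic50) - orc[["logic50"]]), 0.01)
  expect_lt(abs(fit$hill - orc[["hill"]]), 0.01)
  expect_lte(fit$rss, orc[["sse"]] + 1e-8)
})

test_that("fits on random noise-free curves match the grid oracle", {
  set.seed(3)
  for (i in 1:20) {
    truth <- rand_truth()
    s <- exact_series(truth)
    fit <- fit_four_pl(s)
    orc <- grid_fit_oracle(s$data$dose, s$data$viability,
                           top = truth$top, bottom = truth$bottom)
    expect_lt(abs(log10(fit$ic50) - orc[["logic50"]]), 0.01)
    expect_lt(abs(fit$hill - orc[["hill"]]), 0.01)
  }
})

test_that("a Saracatinib-like IC50 spread is recovered in rank order", {
  ic50s <- 10^seq(log10(0.15), log10(33), length.out = 10)
  fits <- lapply(seq_along(ic50s), function(i) {
    truth <- list(top = 100, bottom = 5, ic50 = ic50s[i], hill = 1.1)
    fit_four_pl(simulate_single_agent(truth, HALF_LOG_GRID, 0.05, 3,
                                      seed = 100 + i))
  })
  expect_true(all(vapply(fits, `[[`, logical(1), "converged")))
  est <- vapply(fits, `[[`, numeric(1), "ic50")
  expect_identical(order(est), seq_along(ic50s))
})

test_that("predict_viability evaluates the curve and is monotone", {
  fit <- list(top = 100, bottom = 0, ic50 = 1, hill = 1)
  expect_equal(predict_viability(fit, 1), 50)
  expect_equal(predict_viability(fit, 0), 100)
  expect_equal(predict_viability(fit, 4), 20)

  set.seed(5)
  for (i in 1:25) {
    p <- rand_truth(bottom_max = 30, hill = c(0.2, 6))
    d <- sort(10^runif(40, -3, 3))
    v <- predict_viability(p, d)
    expect_true(all(diff(v) <= 1e-12))
  }
})

test_that("dose_at_inhibition inverts the curve with censoring rules", {
  fit <- exact_fit(list(top = 100, bottom = 0, ic50 = 1, hill = 1))
  expect_equal(dose_at_inhibition(fit, 50)$dose, 1, tolerance = 1e-6)
  expect_equal(dose_at_inhibition(fit, 80)$dose, 4, tolerance = 1e-6)

  shallow <- exact_fit(list(top = 100, bottom = 30, ic50 = 1, hill = 1))
  res <- dose_at_inhibition(shallow, 80)
  expect_false(res$attainable)
  expect_true(is.na(res$dose))
  # attainability margin: 2 points below max inhibition is the edge
  expect_false(dose_at_inhibition(shallow, 69)$attainable)
  expect_true(dose_at_inhibition(shallow, 67)$attainable)

  # IC90 of a resistant line exceeds 10x the top tested dose -> censored
  res_fit <- exact_fit(list(top = 100, bottom = 0, ic50 = 200, hill = 1))
  res <- dose_at_inhibition(res_fit, 90)
  expect_true(res$censored)
  expect_equal(res$dose, 10 * 100)   # extrapolation_limit * max dose
})

test_that("round trip: inhibition level -> dose -> inhibition level", {
  set.seed(9)
  for (i in 1:25) {
    truth <- rand_truth(bottom_max = 20, hill = c(0.3, 4))
    fit <- exact_fit(truth)
    for (y in c(50, 65, 77)) {
      inv <- dose_at_inhibition(fit, y, extrapolation_limit = 1e6)
      if (!inv$attainable) next
      expect_equal(100 - predict_viability(fit, inv$dose), y,
                   tolerance = 1e-6)
    }
  }
})

test_that("sensitivity classification matches the printed thresholds", {
  cases <- list(
    list(ic50 = 0.15, lab = "sensitive"),      # PC-9-like
    list(ic50 = 33,   lab = "resistant"),      # H460-like
    list(ic50 = 5,    lab = "intermediate"),
    list(ic50 = 1.999, lab = "sensitive"),
    list(ic50 = 2,    lab = "intermediate"),   # strict inequality
    list(ic50 = 10,   lab = "intermediate"),
    list(ic50 = 10.001, lab = "resistant"))
  for (cs in cases)
    expect_identical(classify_sensitivity(cs$ic50)$label, cs$lab)
  expect_identical(classify_sensitivity(1000, censored = TRUE)$label,
                   "resistant")
  expect_error(classify_sensitivity(0), "positive")
  expect_error(classify_sensitivity(-1), "positive")
})

test_that("invalid designs are rejected with clear errors", {
  expect_error(fit_four_pl(dose_series("x", c(0.1, 1, 10), c(90, 50, 10))),
               "4 distinct doses")
  expect_error(
    fit_four_pl(dose_series("x", HALF_LOG_GRID, rep(80, 9))),
    "degenerate")
  expect_error(dose_series("x", c(1, -2, 3), c(1, 2, 3)), "positive")
  expect_error(dose_series("x", c(1, 2), c(1, NA)), "finite")
  fit <- exact_fit(list(top = 100, bottom = 0, ic50 = 1, hill = 1))
  fit$converged <- FALSE
  expect_error(dose_at_inhibition(fit, 50), "converged")
})
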