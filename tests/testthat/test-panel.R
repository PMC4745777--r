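build_test_panel <- function(pd_ic50, az_ic50, kappa_by_ratio,
                             noise_cv = 0, n_replicates = 1, seed = 1) {
  # one row set per line; kappa_by_ratio: named list ratio -> kappa vector
  rows <- list()
  for (i in seq_along(pd_ic50)) {
    ln <- sprintf("L%02d", i)
    tpd <- list(top = 100, bottom = 0, ic50 = pd_ic50[i], hill = 1.1)
    taz <- list(top = 100, bottom = 0, ic50 = az_ic50[i], hill = 1.0)
    rows[[length(rows) + 1L]] <- panel_rows(
      ln, "PD", NA_real_,
      simulate_single_agent(tpd, HALF_LOG_GRID, noise_cv, n_replicates,
                            seed + 7 * i))
    rows[[length(rows) + 1L]] <- panel_rows(
      ln, "AZ", NA_real_,
      simulate_single_agent(taz, HALF_LOG_GRID, noise_cv, n_replicates,
                            seed + 7 * i + 1))
    for (r in names(kappa_by_ratio)) {
      rv <- as.numeric(r)
      rows[[length(rows) + 1L]] <- panel_rows(
        ln, "COMBO", rv,
        simulate_combination(tpd, taz, rv, kappa_by_ratio[[r]][i],
                             WIDE_COMBO_GRID, noise_cv, n_replicates,
                             seed + 7 * i + 2))
    }
  }
  do.call(rbind, rows)
}

test_that("screen_panel recovers constructed ground truth exactly", {
  # 8 lines: 3 PD-sensitive, 2 intermediate, 3 resistant by construction;
  # kappa puts 2 strong / 2 synergistic / 3 additive / 1 antagonistic
  pd <- c(0.2, 0.5, 1.5, 4, 8, 20, 50, 90)
  az <- c(0.5, 1, 2.5, 3, 5, 8, 15, 25)
  kap <- list("0.25" = c(0.3, 0.45, 0.6, 0.7, 0.9, 1.0, 1.1, 1.4))
  data <- build_test_panel(pd, az, kap)
  panel <- screen_panel(data)

  pd_counts <- sensitivity_summary(panel, "PD")
  expect_equal(pd_counts$n_sensitive, 3)
  expect_equal(pd_counts$n_intermediate, 2)
  expect_equal(pd_counts$n_resistant, 3)
  expect_equal(pd_counts$n_sensitive + pd_counts$n_intermediate +
                 pd_counts$n_resistant, 8)

  syn <- panel$synergy_counts
  expect_equal(syn$n_strong, 2)
  expect_equal(syn$n_synergistic, 4)   # strong or synergism
  expect_equal(syn$n_additive, 3)
  expect_equal(syn$n_antagonistic, 1)
  expect_equal(syn$n, 8)

  est <- panel$ci[order(panel$ci$cell_line), "median_ci"]
  expect_equal(est, kap[["0.25"]], tolerance = 0.02)
})

test_that("sham panels come out additive everywhere", {
  pd <- c(0.8, 2, 5)
  data <- build_test_panel(pd, pd, list("0.25" = c(1, 1, 1)))
  panel <- screen_panel(data)
  expect_true(all(panel$ci$synergy_class == "additive"))
  expect_equal(panel$synergy_counts$n_additive, 3)
})

test_that("percentages are round-half-up integers as reported", {
  expect_identical(loewescreen:::pct_round(8, 28), 29L)
  expect_identical(loewescreen:::pct_round(19, 28), 68L)
  expect_identical(loewescreen:::pct_round(15, 28), 54L)
  expect_identical(loewescreen:::pct_round(9, 28), 32L)
  expect_identical(loewescreen:::pct_round(11, 28), 39L)
  expect_identical(loewescreen:::pct_round(26, 28), 93L)
  expect_identical(loewescreen:::pct_round(0, 28), 0L)
  expect_identical(loewescreen:::pct_round(1, 28), 4L)
})

test_that("optimal ratio selection counts synergistic lines first", {
  # kappa 0.5 at ratio 0.25 vs 0.9 at ratios 1 and 4 -> pick 0.25
  pd <- c(0.5, 1, 2)
  az <- c(1, 2, 4)
  kap <- list("0.25" = rep(0.5, 3), "1" = rep(0.9, 3), "4" = rep(0.9, 3))
  panel <- screen_panel(build_test_panel(pd, az, kap))
  expect_equal(select_optimal_ratio(panel), 0.25)
  expect_equal(panel$optimal_ratio, 0.25)
})

test_that("optimal-ratio ties break by median CI then by smaller ratio", {
  mk <- function(df) structure(list(ci = df), class = "panel_result")
  # identical synergy counts and medians -> smallest ratio
  df <- data.frame(cell_line = rep(c("a", "b"), 3),
                   ratio = rep(c(0.25, 1, 4), each = 2),
                   median_ci = rep(0.6, 6),
                   synergy_class = "synergism")
  expect_equal(select_optimal_ratio(mk(df)), 0.25)
  # same counts, lower median wins
  df$median_ci[df$ratio == 4] <- 0.55
  expect_equal(select_optimal_ratio(mk(df)), 4)
  # a ratio with no valid summaries is never selected
  df2 <- data.frame(cell_line = "a", ratio = c(0.25, 1, 4),
                    median_ci = c(NA, 0.6, NA),
                    synergy_class = c(NA, "synergism", NA))
  expect_equal(select_optimal_ratio(mk(df2)), 1)
})

test_that("class counts conserve the panel size for every condition", {
  spec <- synthetic_panel_spec(n_lines = 6, ratio_set = 0.25,
                               noise_cv = 0.03, seed = 42)
  panel <- screen_panel(simulate_panel(spec)$data)
  for (i in seq_len(nrow(panel$counts))) {
    row <- panel$counts[i, ]
    expect_equal(row$n_sensitive + row$n_intermediate + row$n_resistant,
                 row$n)
  }
})

test_that("row order of the input table does not change the result", {
  data <- build_test_panel(c(0.5, 5), c(1, 8),
                           list("0.25" = c(0.5, 1)),
                           noise_cv = 0.05, n_replicates = 3)
  set.seed(99)
  shuffled <- data[sample(nrow(data)), ]
  p1 <- screen_panel(data)
  p2 <- screen_panel(shuffled)
  expect_equal(p1$fits, p2$fits, ignore_attr = TRUE)
  expect_equal(p1$ci, p2$ci, ignore_attr = TRUE)
  expect_equal(p1$counts, p2$counts, ignore_attr = TRUE)
})

test_that("missing single agents are logged, not silently dropped", {
  data <- build_test_panel(c(0.5, 5), c(1, 8), list("0.25" = c(0.5, 1)))
  data <- data[!(data$cell_line == "L02" & data$condition == "AZ"), ]
  panel <- screen_panel(data)
  ex <- panel$exclusions
  expect_true(any(ex$cell_line == "L02" & ex$condition == "AZ"))
  expect_true(any(ex$cell_line == "L02" & ex$condition == "COMBO"))
  # line L01 is unaffected
  expect_true("L01" %in% panel$ci$cell_line)
  expect_false("L02" %in% panel$ci$cell_line)
  expect_error(sensitivity_summary(panel, "nope"), "unknown condition")
})
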