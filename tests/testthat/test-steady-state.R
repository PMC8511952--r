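test_that("initial rate of an exact line is its slope", {
  t <- seq(0, 60, by = 5)
  curve <- progress_curve(t, 0.01 * t, substrate_uM = 10, enzyme_uM = 0.1)
  expect_equal(extract_initial_rate(curve, 0.10), 0.01)
})

test_that("null and inverted signals are handled with flags, short windows error", {
  t <- seq(0, 60, by = 5)
  flat <- progress_curve(t, rep(0, length(t)), 10, 0.1)
  expect_warning(r <- extract_initial_rate(flat), "degenerate")
  expect_identical(r, 0)
  down <- progress_curve(t, pmax(0.5 - 0.005 * t, 0), 10, 0.1)
  expect_warning(r2 <- extract_initial_rate(down), "negative")
  expect_identical(r2, 0)
  short <- progress_curve(c(0, 1, 2, 10, 20), c(0, 0.1, 0.2, 5, 9), 10, 0.1)
  expect_error(extract_initial_rate(short), "fewer than 4")
})

test_that("low-conversion rate from an integrated MM curve matches the analytic velocity", {
  # low-substrate regime of the reference enzyme: 0.1 uM tRNA, 4 nM enzyme
  kcat <- 0.167; KM <- 1.62; S0 <- 0.1; E0 <- 0.004
  v_true <- mm_velocity(S0, kcat, KM, E0)
  t <- seq(0, 0.04 * S0 / v_true, length.out = 12)
  curve <- progress_curve(t, integrated_mm_product(t, kcat, KM, E0, S0),
                          S0, E0)
  expect_equal(extract_initial_rate(curve, 0.05), v_true, tolerance = 0.02)
})

test_that("low-substrate rates are proportional to catalytic efficiency", {
  kcat <- 0.167; KM <- 1.62; E0 <- 0.004
  for (S0 in KM / c(50, 200)) {
    v_true <- mm_velocity(S0, kcat, KM, E0)
    t <- seq(0, 0.03 * S0 / v_true, length.out = 12)
    curve <- progress_curve(t, integrated_mm_product(t, kcat, KM, E0, S0),
                            S0, E0)
    expect_equal(extract_initial_rate(curve, 0.04) / (E0 * S0), kcat / KM,
                 tolerance = 0.05)
  }
})

test_that("MM fit recovers generating parameters from noiseless rates on both designs", {
  cases <- list(
    list(kcat = 0.167, KM = 1.62, S = c(0.5, 1, 2, 4, 8, 16), E0 = 0.1),
    list(kcat = 0.019, KM = 0.235, S = c(0.063, 0.125, 0.25, 0.5, 1, 2),
         E0 = 0.01))
  for (cs in cases) {
    v <- mm_velocity(cs$S, cs$kcat, cs$KM, cs$E0)
    fit <- fit_michaelis_menten(cs$S, v, cs$E0)
    expect_equal(fit$kcat, cs$kcat, tolerance = 1e-3)
    expect_equal(fit$KM, cs$KM, tolerance = 1e-3)
    expect_equal(fit$kcat_over_KM, cs$kcat / cs$KM, tolerance = 1e-3)
    expect_true(fit$converged)
    expect_true(fit$reliable)
  }
})

test_that("round-trip recovery within 0.5% across a parameter sweep", {
  for (kcat in c(0.02, 0.2, 2)) {
    for (KM in c(0.1, 1, 10)) {
      S <- KM * c(0.25, 0.5, 1, 2, 4)
      v <- mm_velocity(S, kcat, KM, 0.05)
      fit <- fit_michaelis_menten(S, v, 0.05)
      expect_equal(fit$kcat, kcat, tolerance = 5e-3)
      expect_equal(fit$KM, KM, tolerance = 5e-3)
    }
  }
})

test_that("purely linear v(S) is flagged unidentifiable", {
  S <- c(0.1, 0.2, 0.4, 0.8, 1.6)
  expect_warning(fit <- fit_michaelis_menten(S, 0.01 * S, 0.1),
                 "unreliable")
  expect_false(fit$reliable)
})

test_that("median recovered kcat is unbiased under 5% relative noise (200 seeds)", {
  kcat <- 0.167; KM <- 1.62; E0 <- 0.1
  S <- c(0.5, 1, 2, 4, 8, 16)
  v0 <- mm_velocity(S, kcat, KM, E0)
  est <- vapply(seq_len(200), function(seed) {
    set.seed(seed)
    v <- v0 * (1 + rnorm(length(v0), 0, 0.05))
    fit_michaelis_menten(S, v, E0)$kcat
  }, numeric(1))
  expect_equal(median(est), kcat, tolerance = 0.03)
})

test_that("replicate summaries aggregate and fold-change correctly", {
  mk <- function(kcat, KM, label) {
    S <- KM * c(0.25, 0.5, 1, 2, 4)
    fit_michaelis_menten(S, mm_velocity(S, kcat, KM, 0.1), 0.1, label = label)
  }
  fits <- list(mk(0.167, 1.62, "WT"), mk(0.167, 1.62, "WT"),
               mk(0.019, 0.235, "P14R"))
  s <- summarize_replicates(fits, "WT")
  expect_equal(s$fold_decrease_kcat[s$label == "P14R"], 0.167 / 0.019,
               tolerance = 1e-3)
  expect_equal(signif(s$fold_decrease_kcat[s$label == "P14R"], 2), 8.8)
  # reference vs itself is exactly 1; single replicate has NA spread
  expect_equal(s$fold_decrease_kcat[s$label == "WT"], 1)
  expect_true(is.na(s$kcat_sd[s$label == "P14R"]))
  expect_false(is.na(s$kcat_sd[s$label == "WT"]))
  expect_error(summarize_replicates(fits, "E205G"), "unknown reference")
})
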