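test_that("depletion isotherm limits and frozen quadratic value", {
  # half-saturation in the vanishing-ligand limit
  expect_equal(fraction_bound_depletion(83.7, 1e-9, 83.7), 0.5,
               tolerance = 1e-6)
  expect_identical(fraction_bound_depletion(0, 5, 83.7), 0)
  # L = 0 handled by the limit expression
  expect_equal(fraction_bound_depletion(10, 0, 10), 0.5)
  # value frozen from the root-bracketing oracle at the reference design
  # (P = Kd = 83.7 nM, 5 nM labeled tRNA)
  expect_equal(fraction_bound_depletion(83.7, 5, 83.7), 0.4925345,
               tolerance = 1e-6)
})

test_that("the quadratic root agrees with the equilibrium oracle and stays physical", {
  set.seed(42)
  for (i in 1:200) {
    P <- runif(1, 0, 1000); L <- runif(1, 0.01, 100); Kd <- runif(1, 0.1, 500)
    f <- fraction_bound_depletion(P, L, Kd)
    expect_gte(f, 0)
    expect_lte(f, min(1, P / L) + 1e-12)
    expect_equal(f, oracle_fraction_bound(P, L, Kd), tolerance = 1e-8)
  }
})

test_that("anisotropy mixing endpoints and midpoint", {
  expect_equal(anisotropy_signal(0, 0.05, 0.15), 0.05)
  expect_equal(anisotropy_signal(1, 0.05, 0.15), 0.15)
  expect_equal(anisotropy_signal(0.5, 0.05, 0.15, q = 1), 0.10)
  # q weights the bound contribution
  expect_gt(anisotropy_signal(0.5, 0.05, 0.15, q = 2), 0.10)
})

test_that("binding fit recovers Kd from noiseless titrations within 0.5%", {
  for (Kd in c(83.7, 331, 54.3, 277, 94)) {
    P <- Kd / 10 * 2^(0:9)
    r <- anisotropy_signal(fraction_bound_depletion(P, 5, Kd), 0.05, 0.18)
    fit <- fit_binding_curve(titration_curve(P, r, ligand_nM = 5))
    expect_equal(fit$Kd, Kd, tolerance = 5e-3)
    expect_true(fit$converged)
    expect_true(fit$reliable)
  }
})

test_that("the WHEP-domain affinity ratio rounds to 4-fold", {
  fit_kd <- function(Kd) {
    P <- Kd / 10 * 2^(0:9)
    r <- anisotropy_signal(fraction_bound_depletion(P, 5, Kd), 0.05, 0.18)
    fit_binding_curve(titration_curve(P, r, ligand_nM = 5))$Kd
  }
  expect_equal(round(fit_kd(331) / fit_kd(83.7)), 4)
})

test_that("depletion and simple-hyperbola fits agree when ligand << Kd", {
  Kd <- 83.7; L <- 5   # L <= Kd/16: depletion correction is small
  P <- Kd / 10 * 2^(0:9)
  r <- anisotropy_signal(fraction_bound_depletion(P, L, Kd), 0.05, 0.18)
  hyp <- minpack.lm::nlsLM(
    r ~ rf + (rb - rf) * P / (P + K),
    data = data.frame(P = P, r = r),
    start = list(K = 50, rf = min(r), rb = max(r)))
  expect_equal(coef(hyp)[["K"]], Kd, tolerance = 0.03)
})

test_that("inverted titrations are flagged unreliable", {
  P <- 8.37 * 2^(0:9)
  r <- anisotropy_signal(fraction_bound_depletion(P, 5, 83.7), 0.18, 0.05)
  expect_warning(fit <- fit_binding_curve(titration_curve(P, r)),
                 "unreliable")
  expect_false(fit$reliable)
})

test_that("noisy-titration Kd recovery is accurate to 10% in the mean (200 seeds)", {
  Kd <- 83.7
  P <- Kd / 10 * 2^(0:9)
  r0 <- anisotropy_signal(fraction_bound_depletion(P, 5, Kd), 0.05, 0.18)
  est <- vapply(1:200, function(seed) {
    set.seed(seed)
    r <- pmin(pmax(r0 + rnorm(length(r0), 0, 0.005), 1e-4), 0.4)
    fit_binding_curve(titration_curve(P, r))$Kd
  }, numeric(1))
  expect_equal(mean(est), Kd, tolerance = 0.10)
  expect_gt(sd(est), 0)
})
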