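test_that("generators are byte-identical under a fixed seed and vary across seeds", {
  spec <- scenario_spec("WT", truth = list(kcat = 0.167, KM = 1.62))
  nm <- noise_model("gaussian_relative", 0.05, seed = 17)
  a <- generate_aminoacylation_dataset(spec, nm)
  b <- generate_aminoacylation_dataset(spec, nm)
  expect_identical(a, b)
  c <- generate_aminoacylation_dataset(spec,
                                       noise_model("gaussian_relative", 0.05,
                                                   seed = 18))
  expect_false(identical(a, c))

  tspec <- scenario_spec("WT", truth = list(Kd = 83.7))
  tn <- noise_model("gaussian_absolute", 0.005, seed = 17)
  expect_identical(generate_titration(tspec, tn), generate_titration(tspec, tn))

  mspec <- scenario_spec("WT", truth = list(Tm = 44.7, n = 10.7))
  mn <- noise_model("gaussian_absolute", 0.16, seed = 17)
  expect_identical(generate_melting(mspec, mn), generate_melting(mspec, mn))
})

test_that("generation does not disturb the session RNG stream", {
  set.seed(99); before <- rnorm(3)
  set.seed(99); invisible(rnorm(1))
  invisible(generate_titration(scenario_spec("WT", list(Kd = 83.7)),
                               noise_model("gaussian_absolute", 0.005, 5)))
  after <- c(rnorm(2))
  expect_identical(before[2:3], after)
})

test_that("noise-free aminoacylation data round-trip the generating MM truth", {
  spec <- scenario_spec("WT", truth = list(kcat = 0.167, KM = 1.62),
                        design = list(n_time = 30L))
  curves <- generate_aminoacylation_dataset(spec, noise_model(sigma = 0))
  rates <- vapply(curves, extract_initial_rate, numeric(1),
                  max_conversion_fraction = 0.05)
  S <- vapply(curves, function(cv) cv$substrate_uM[1], numeric(1))
  fit <- fit_michaelis_menten(S, rates, enzyme_total = 0.1)
  # the OLS window carries a small substrate-depletion bias (~half the
  # conversion cap), so recovery is a few percent, not exact
  expect_equal(fit$kcat, 0.167, tolerance = 0.02)
  expect_equal(fit$KM, 1.62, tolerance = 0.03)
})

test_that("mechanistic truth is accepted by the aminoacylation generator", {
  spec <- scenario_spec("WT-mech", truth = list(rates = default_rates("WT")),
                        design = list(substrate_uM = c(0.5, 2, 8),
                                      n_time = 8L))
  curves <- generate_aminoacylation_dataset(spec, noise_model(sigma = 0))
  expect_length(curves, 3L)
  for (cv in curves) {
    expect_identical(cv$product_uM[1], 0)
    expect_true(all(diff(cv$product_uM) >= 0))
  }
})

test_that("titration design saturates and round-trips Kd", {
  spec <- scenario_spec("WT", truth = list(Kd = 83.7))
  curves <- generate_titration(spec, noise_model(sigma = 0))
  cv <- curves[[1]]
  # design adequacy: top of the default grid is > 95% bound
  f_top <- fraction_bound_depletion(max(cv$protein_nM), 5, 83.7)
  expect_gt(f_top, 0.95)
  fit <- fit_binding_curve(cv)
  expect_equal(fit$Kd, 83.7, tolerance = 5e-3)
})

test_that("three noisy titration replicates give positive Kd spread, mean within 10%", {
  spec <- scenario_spec("WT", truth = list(Kd = 83.7),
                        design = list(replicates = 3L))
  curves <- generate_titration(spec,
                               noise_model("gaussian_absolute", 0.005, 11))
  kds <- vapply(curves, function(cv) fit_binding_curve(cv)$Kd, numeric(1))
  expect_gt(sd(kds), 0)
  expect_equal(mean(kds), 83.7, tolerance = 0.10)
})

test_that("melting generator uses the standard 36-point grid and round-trips", {
  spec <- scenario_spec("WT", truth = list(Tm = 44.7, n = 10.7))
  curves <- generate_melting(spec, noise_model(sigma = 0))
  expect_identical(nrow(curves[[1]]), 36L)
  fit <- fit_melting_curve(curves[[1]])
  expect_equal(fit$Tm, 44.7, tolerance = 5e-3)
  expect_equal(fit$n, 10.7, tolerance = 5e-3)
})

test_that("exchange generator: 6-point design, increasing WT label, suppressed mutant", {
  wt <- generate_exchange(scenario_spec("WT",
                                        list(rates = default_rates("WT"))),
                          noise_model(sigma = 0))
  expect_identical(nrow(wt[[1]]), 6L)
  expect_true(all(diff(wt[[1]]$frac_atp) > 0))
  mut <- generate_exchange(scenario_spec("P14R",
                                         list(rates = default_rates("P14R"))),
                           noise_model(sigma = 0))
  expect_lt(tail(mut[[1]]$frac_atp, 1), 0.2 * tail(wt[[1]]$frac_atp, 1))
})

test_that("noise draws never leave the physical ranges", {
  spec <- scenario_spec("X", truth = list(Kd = 20))
  curves <- generate_titration(spec, noise_model("gaussian_absolute", 0.05,
                                                 seed = 3))
  expect_true(all(curves[[1]]$anisotropy > 0 & curves[[1]]$anisotropy <= 0.4))
  aspec <- scenario_spec("X", truth = list(kcat = 0.167, KM = 1.62),
                         design = list(substrate_uM = c(0.5, 1, 2, 4, 8, 16)))
  ac <- generate_aminoacylation_dataset(aspec,
                                        noise_model("gaussian_relative", 0.5,
                                                    seed = 3))
  for (cv in ac)
    expect_true(all(cv$product_uM >= 0 &
                      cv$product_uM <= cv$substrate_uM[1]))
})
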