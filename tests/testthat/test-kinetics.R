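test_that("noiseless Michaelis-Menten data are recovered near-exactly", {
  for (truth in list(c(kcat = 0.7, KM = 2.1), c(kcat = 0.013, KM = 18))) {
    series <- gen_kinetics(truth[["kcat"]], truth[["KM"]], enzyme_conc = 0.5,
                           cv = 0, seed = 1)
    fit <- fit_michaelis_menten(series)
    expect_equal(fit$kcat, truth[["kcat"]], tolerance = 1e-3)
    expect_equal(fit$KM, truth[["KM"]], tolerance = 1e-3)
    expect_equal(fit$efficiency, truth[["kcat"]] / truth[["KM"]],
                 tolerance = 1e-3)
  }
  # the low-efficiency enzyme computes to ~7e-4 uM^-1 s^-1
  fit <- fit_michaelis_menten(gen_kinetics(0.013, 18, cv = 0, seed = 1))
  expect_equal(signif(fit$efficiency, 1), 7e-4)
})

test_that("a saturating-only concentration grid leaves KM unidentifiable", {
  kcat <- 0.7
  KM <- 2.1
  S <- c(50, 100, 150, 200, 300, 400)  # all >> KM
  v <- kcat * 1 * S / (KM + S)
  series <- rate_series(S, v, enzyme_conc = 1)
  expect_error(fit_michaelis_menten(series), "unidentifiable")
  expect_error(
    fit_michaelis_menten(rate_series(c(1, 2, 4), kcat * c(1, 2, 4) /
                                       (KM + c(1, 2, 4)), 1)),
    ">= 5")
})

test_that("rate series validate their inputs", {
  expect_error(rate_series(c(1, 2), c(1, 2, 3), 1), "equal length")
  expect_error(rate_series(c(0, 2), c(1, 2), 1), "positive")
  expect_error(rate_series(c(2, 2), c(1, 2), 1), "distinct")
})

test_that("efficiency comparison reproduces the printed substrate folds", {
  # printed parameters for the fast paralog: NADPH 0.7/2.1 (eff 0.3),
  # NADH 0.23/22 (printed eff 6e-2)
  b2_nadph <- kinetic_params(0.7, 2.1, "NADPH", efficiency = 0.3)
  b2_nadh <- kinetic_params(0.23, 22, "NADH", efficiency = 6e-2)
  cmp <- compare_efficiencies(b2_nadph, b2_nadh)
  expect_equal(cmp$fold, 5)
  expect_equal(cmp$preferred, "NADPH")
  expect_equal(cmp$kcat_fold, 0.7 / 0.23, tolerance = 1e-6)
  # the slow paralog shows no discrimination under the 1.5-fold band
  b1_nadph <- kinetic_params(0.013, 18, "NADPH", efficiency = 7e-4)
  b1_nadh <- kinetic_params(0.013, 21, "NADH", efficiency = 6e-4)
  cmp1 <- compare_efficiencies(b1_nadph, b1_nadh)
  expect_lt(cmp1$fold, 1.5)
  expect_equal(cmp1$preferred, "none")
  # identical fits compare to exactly 1
  expect_equal(compare_efficiencies(b2_nadph, b2_nadph)$fold, 1.0)
})

test_that("efficiency folds are reciprocal-consistent", {
  a <- kinetic_params(0.7, 2.1, "NADPH")
  b <- kinetic_params(0.23, 22, "NADH")
  ab <- compare_efficiencies(a, b)
  ba <- compare_efficiencies(b, a)
  expect_equal(ab$fold, ba$fold)
  expect_equal(ab$direction * ba$direction, -1)
})

test_that("Hill fits recover cooperative binding parameters", {
  exact <- gen_binding_titration(K_half = 3, hill_n = 2, amplitude = 10,
                                 cv = 0, seed = 5)
  fit <- fit_hill(exact$conc, exact$delta_f)
  expect_equal(fit$K_half, 3, tolerance = 0.01)
  expect_equal(fit$hill_n, 2, tolerance = 0.01)
  expect_equal(fit$amplitude, 10, tolerance = 0.05)
  noisy <- gen_binding_titration(K_half = 5, hill_n = 2, amplitude = 10,
                                 cv = 0.03, seed = 17)
  fitn <- fit_hill(noisy$conc, noisy$delta_f)
  expect_lt(abs(fitn$K_half - 5) / 5, 0.10)
})

test_that("a Hill fit with n fixed to 1 is the rectangular hyperbola", {
  kcat <- 0.4
  KM <- 6
  series <- gen_kinetics(kcat, KM, enzyme_conc = 2, cv = 0, seed = 3)
  hyp <- fit_hill(series$substrate_conc, series$initial_rate, fix_n = 1)
  mm <- fit_michaelis_menten(series)
  expect_equal(hyp$K_half, mm$KM, tolerance = 1e-4)
  expect_equal(hyp$amplitude, mm$kcat * 2, tolerance = 1e-4)
})

test_that("relative D content normalises to adenosine and to the reference", {
  same <- relative_d_content(50, 25, 50, 25)
  expect_equal(same$relative_D, 100)
  gone <- relative_d_content(0, 30, 50, 25)
  expect_equal(gone$relative_D, 0)
  # a knockout panel built at 66/82/0% of wild type reports those values
  ref_d <- 80; ref_a <- 40
  panel <- relative_d_content(
    d_signal = c(ref_d, 0.66 * ref_d, 0.82 * ref_d, 0),
    adenosine_uv = rep(ref_a, 4), reference_d = ref_d,
    reference_adenosine = ref_a,
    strain = c("WT", "dB1", "dB2", "dB1dB2"))
  expect_equal(panel$relative_D, c(100, 66, 82, 0))
  # invariance to common rescaling of all raw signals
  scaled <- relative_d_content(
    d_signal = c(ref_d, 0.66 * ref_d, 0.82 * ref_d, 0) * 3.7,
    adenosine_uv = rep(ref_a, 4) * 3.7, reference_d = ref_d * 3.7,
    reference_adenosine = ref_a * 3.7)
  expect_equal(scaled$relative_D, panel$relative_D)
  expect_error(relative_d_content(10, 10, 0, 10), "reference")
})

test_that("A340 slopes convert through Beer-Lambert", {
  # dA/dt of 0.00622 per second over 6220 M^-1 cm^-1, 1 cm path = 1 uM/s
  expect_equal(a340_slope_to_rate(-0.00622), 1.0)
})

test_that("kinetics tables and reports round-trip", {
  dir <- withr::local_tempdir()
  tsv <- file.path(dir, "rates.tsv")
  s <- gen_kinetics(0.7, 2.1, enzyme_conc = 0.5, cv = 0, seed = 2)
  write.table(data.frame(substrate = "NADPH", conc_uM = s$substrate_conc,
                         rate = s$initial_rate),
              tsv, sep = "\t", quote = FALSE, row.names = FALSE)
  series <- read_kinetics_table(tsv, enzyme_conc = 0.5)
  fits <- lapply(series, fit_michaelis_menten)
  json <- file.path(dir, "fits.json")
  write_kinetics_report(fits, json)
  back <- jsonlite::read_json(json)
  expect_equal(back$NADPH$kcat_per_s, 0.7, tolerance = 1e-3)
  expect_equal(back$NADPH$KM_uM, 2.1, tolerance = 1e-3)
})
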