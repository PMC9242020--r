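test_that("E and S follow the corrected ALEX formulas", {
  b <- tibble::tibble(I_DD = 60, I_DA = 40, I_AA = 50, duration_ms = 1)

  plain <- compute_es(b)
  expect_equal(plain$E, 0.4)
  expect_equal(plain$S, 100 / 150)

  corr <- correction_factors(gamma = 1, leakage = 0.1,
                             direct_excitation = 0.05)
  # F = 40 - 0.1*60 - 0.05*50 = 31.5; E = 31.5 / (60 + 31.5)
  with_corr <- compute_es(b, corr)
  expect_equal(with_corr$E, 31.5 / 91.5)

  # donor-only burst: no acceptor signal at all -> S = 1
  donly <- compute_es(tibble::tibble(I_DD = 80, I_DA = 0, I_AA = 0))
  expect_equal(donly$S, 1)

  # zero corrected denominator -> flagged invalid, NA E/S
  degen <- compute_es(tibble::tibble(I_DD = 0, I_DA = 0, I_AA = 10))
  expect_false(degen$es_valid)
  expect_true(is.na(degen$E))
})

test_that("burst selection applies strict rate and stoichiometry gates", {
  b <- tibble::tibble(
    I_DD = c(10, 50, 40, 40), I_DA = c(10, 50, 0, 10),
    I_AA = c(5, 40, 0, 350), duration_ms = c(1, 1, 1, 1))
  es <- compute_es(b)
  # burst 1: 25 photons/ms -> rate gate; burst 3: S = 1 donor-only side;
  # (burst 3 carries 40 photons so only the stoichiometry gate removes it)
  # burst 4: S = 50/400 = 0.125 acceptor-heavy; burst 2 kept (S = 0.714)
  es$S[2] <- 0.5  # place squarely inside the window
  kept <- select_bursts(es)
  expect_equal(nrow(kept), 1)
  expect_equal(kept$I_DD, 50)
  counts <- attr(kept, "filter_counts")
  expect_equal(unname(counts["rate"]), 1)
  expect_equal(unname(counts["stoichiometry"]), 2)

  # filtering is idempotent and never increases the count
  again <- select_bursts(kept)
  expect_equal(nrow(again), nrow(kept))
  expect_lte(nrow(kept), nrow(es))

  # boundary values are excluded (strict inequalities)
  edge <- compute_es(tibble::tibble(I_DD = 30, I_DA = 0, I_AA = 0,
                                    duration_ms = 1))
  expect_equal(nrow(select_bursts(edge)), 0)
})

test_that("histogram uses half-open bins with a closed last bin", {
  h <- histogram_1d(c(0.1, 0.1, 0.9), breaks = c(0, 0.5, 1))
  expect_equal(h$count, c(2, 1))
  # value on an internal edge goes right; top edge stays in the last bin
  h2 <- histogram_1d(c(0.5, 1.0), breaks = c(0, 0.5, 1))
  expect_equal(h2$count, c(0, 2))
  # conservation of in-range values
  set.seed(8)
  x <- rnorm(500, 0.5, 0.5)
  h3 <- histogram_1d(x)
  expect_equal(sum(h3$count), sum(x >= -0.1 & x <= 1.1))
  expect_error(histogram_1d(numeric(0)), "No finite")
})

test_that("single-Gaussian fits recover a known center", {
  set.seed(11)
  # multinomial draw from a Gaussian at the weakly-bent construct's E
  E <- rnorm(1e4, 0.43, 0.1)
  h <- histogram_1d(E)
  fit <- fit_gaussian_mixture(h, 1)
  expect_equal(fit$centers, 0.43, tolerance = 0.01)
  expect_equal(fit$weights, 1)
  # symmetric histogram: fitted center within ~one bin of the mode bin
  expect_lt(abs(fit$centers - h$mid[which.max(h$count)]), 1.5 * 0.024)
})

test_that("two-component fits recover weights and order components by center", {
  set.seed(12)
  n <- 3000
  w_hi <- 0.7
  E <- c(rnorm(round(n * (1 - w_hi)), 0.45, 0.07),
         rnorm(round(n * w_hi), 0.95, 0.05))
  fit <- fit_gaussian_mixture(histogram_1d(E), 2)
  expect_lt(fit$centers[1], fit$centers[2])
  expect_equal(fit$centers, c(0.45, 0.95), tolerance = 0.02)
  expect_equal(fit$weights[2], 0.7, tolerance = 0.02)
  expect_equal(sum(fit$weights), 1, tolerance = 1e-6)
  # too few occupied bins errors
  expect_error(
    fit_gaussian_mixture(histogram_1d(rep(0.5, 50), breaks = c(0, 1)), 2),
    "too few")
})

test_that("kink fraction reads the weight above the center threshold", {
  set.seed(13)
  two <- fit_gaussian_mixture(histogram_1d(
    c(rnorm(900, 0.45, 0.07), rnorm(2100, 0.95, 0.05))), 2)
  expect_equal(kink_fraction(two), two$weights[2])
  expect_equal(kink_fraction(two, threshold_E = 0.99), 0)
  expect_equal(kink_fraction(two, threshold_E = 0.2), 1, tolerance = 1e-6)

  hi <- fit_gaussian_mixture(histogram_1d(rnorm(2000, 0.95, 0.05)), 1)
  expect_equal(kink_fraction(hi), 1)
  lo <- fit_gaussian_mixture(histogram_1d(rnorm(2000, 0.43, 0.1)), 1)
  expect_equal(kink_fraction(lo), 0)
})

test_that("center standard error scales as width over sqrt(n)", {
  se <- center_standard_error(0.11, 3236)
  expect_equal(se, 0.11 / sqrt(3236))
  expect_equal(se, 0.00193, tolerance = 5e-3)
  # quadrupling the burst count halves the precision exactly
  expect_equal(center_standard_error(0.11, 4 * 3236), se / 2)
  expect_equal(center_standard_error(0, 100), 0)
  # also accepts a fitted object
  set.seed(14)
  f <- fit_gaussian_mixture(histogram_1d(rnorm(3000, 0.43, 0.1)), 1)
  expect_equal(center_standard_error(f, 3000), f$widths / sqrt(3000))
})

test_that("corrected E round-trips through the synthetic forward model", {
  # the per-burst corrected E is a ratio estimator with an O(1/N_photons)
  # bias (~0.001 at 100 photons/burst), so the 2-standard-error band is
  # checked in the shot-noise-dominated regime where it is the dominant
  # uncertainty; histogram-level recovery at large n is covered by the
  # +/-0.01 fitted-center checks.
  corr <- correction_factors(gamma = 1, leakage = 0.1,
                             direct_excitation = 0.05)
  for (true_E in c(0.18, 0.43, 0.95)) {
    preset <- scenario_preset("rt", list(species_spec(true_E, "dual")),
                              corrections = corr, n_bursts = 400,
                              seed = 400 + round(100 * true_E))
    b <- select_bursts(compute_es(generate_bursts(preset), corr))
    bias <- mean(b$E) - true_E
    expect_lt(abs(bias), 2 * sd(b$E) / sqrt(nrow(b)))
  }
})

test_that("estimated kink fraction increases with the true mixture weight", {
  est <- vapply(c(0.2, 0.5, 0.8), function(f) {
    b <- generate_kink_mixture(f, n_bursts = 5000, seed = 600 + 10 * f)
    fit <- suppressWarnings(
      fit_gaussian_mixture(histogram_1d(select_bursts(compute_es(b))$E), 2))
    kink_fraction(fit)
  }, numeric(1))
  expect_true(all(diff(est) > 0))
})
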