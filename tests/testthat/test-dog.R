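test_that("the DoG profile matches its closed form and symmetries", {
  p <- dog_params(100, 1, 4, 6)
  grid <- filter_grid(256)
  prof <- dog_profile(p, grid)
  # value at x = 0
  expect_equal(prof[grid$x == 0],
               100 / (4 * sqrt(2 * pi)) - 100 / (4 * 6 * sqrt(2 * pi)))
  # even symmetry (x = -128 has no +128 partner on the grid)
  expect_equal(prof[grid$x == 57], prof[grid$x == -57])
  expect_equal(prof[match(1:127, grid$x)], prof[match(-(1:127), grid$x)])
  # beta = 1 makes the filter d.c.-balanced (up to the truncated surround tail)
  expect_lt(abs(sum(prof)) / max(abs(prof)), 1e-5)
  # truncation warning when the surround spills off the grid
  expect_warning(dog_profile(dog_params(100, 1, 20, 4), grid),
                 "truncated")
  expect_error(dog_profile(dog_params(100, 1, 20, 4), grid,
                           on_truncation = "error"),
               class = "texmod_truncated_profile")
})

test_that("sensitivity predictions agree with the analytic Fourier magnitude", {
  p <- dog_params(100, 0.95, 3, 5)
  s <- predict_sensitivities(p, study_kinds, study_freqs)
  # sinewave responses equal |FT| of the filter at the modulation frequency
  ft <- function(f) {
    nu <- f / 256
    abs(p$alpha * exp(-2 * pi^2 * p$gamma^2 * nu^2) -
          p$alpha * p$beta * exp(-2 * pi^2 * (p$gamma * p$delta)^2 * nu^2))
  }
  for (f in study_freqs) {
    expect_equal(s["SN", as.character(f)], ft(f), tolerance = 1e-6)
  }
  # linearity in alpha
  p2 <- dog_params(200, 0.95, 3, 5)
  expect_equal(predict_sensitivities(p2, study_kinds, study_freqs), 2 * s,
               tolerance = 1e-12)
  # SQ response = SN response + CS response pointwise, so maxima obey the
  # triangle inequality
  expect_true(all(s["SQ", ] <= s["SN", ] + s["CS", ] + 1e-9))
  # frequency axis must match the sensitivity columns
  expect_error(fit_dog(s, c(1, 2)), class = "texmod_invalid_argument")
})

test_that("analytic peak frequency implements the stated formula", {
  p <- dog_params(100, 1, 4, 6)
  expect_equal(peak_sf_analytic(p),
               256 * sqrt(log(1 * 36) / (2 * pi^2 * 16 * 35)))
  # agrees with the DFT argmax within one frequency bin
  expect_lt(abs(peak_sf_analytic(p) - peak_sf_dft(p)), 1)
  # halving gamma doubles the peak frequency
  p_half <- dog_params(100, 1, 2, 6)
  expect_equal(peak_sf_analytic(p_half), 2 * peak_sf_analytic(p))
  # peak is independent of alpha
  expect_equal(peak_sf_analytic(dog_params(7, 1, 4, 6)), peak_sf_analytic(p))
  # beta * delta^2 = 1 degenerates to d.c.
  expect_equal(peak_sf_analytic(dog_params(100, 0.25, 4, 2)), 0)
  expect_error(peak_sf_analytic(dog_params(100, 0.1, 4, 2)),
               class = "texmod_undefined_peak")
  # pure centre Gaussian is low-pass: DFT peak at 0
  expect_equal(peak_sf_dft(dog_params(100, 0, 8, 2)), 0)
})

test_that("analytic and DFT peak estimates agree across the bandpass domain", {
  set.seed(7)
  n_checked <- 0
  while (n_checked < 1000) {
    p <- dog_params(exp(stats::runif(1, log(10), log(1000))),
                    stats::runif(1, 0.5, 1.25),
                    stats::runif(1, 2, 10),
                    stats::runif(1, 1.5, 6))
    if (p$beta * p$delta^2 <= 1.1 || p$gamma * p$delta > 30) next
    n_checked <- n_checked + 1
    expect_lt(abs(peak_sf_analytic(p) - peak_sf_dft(p)), 1)
  }
  # doubling the grid resolution leaves the DFT estimate in place
  p <- dog_params(100, 1, 4, 6)
  expect_equal(peak_sf_dft(p, filter_grid(512)) / 2, peak_sf_dft(p),
               tolerance = 0.05)
})

test_that("filter SDs convert to degrees via the stimulus geometry", {
  p <- dog_params(100, 1, 4, 6)
  sz <- sd_to_degrees(p)
  expect_equal(sz$centre_sd_deg, 10 * 4 / 256)
  expect_equal(sz$surround_sd_deg, sz$centre_sd_deg * 6)
  expect_equal(sz$rf_extent_deg, 5 * 0.9375)
  sz2 <- sd_to_degrees(p, stimulus_geometry(20, 512))
  expect_equal(sz2$centre_sd_deg, 20 * 4 / 512)
})

test_that("R-squared follows the correlation definition", {
  x <- c(1, 2, 3, 5, 8)
  expect_equal(r_squared(x, x), 1)
  flat <- r_squared(rep(2, 5), x)
  expect_equal(as.numeric(flat), 0)
  expect_true(attr(flat, "zero_variance"))
  # cross-check against an independent linear-model fit
  set.seed(2)
  y <- 2 * x + stats::rnorm(5, 0, 0.5)
  expect_equal(r_squared(y, x), summary(stats::lm(y ~ x))$r.squared)
  # sum-of-squares alternative
  expect_equal(r_squared(x, x + 1, method = "ss"),
               1 - 5 / sum((x - mean(x))^2))
  expect_error(r_squared(1:3, 1:4), class = "texmod_invalid_argument")
})

test_that("fitting recovers generating parameters from noise-free data", {
  for (p in regime_params()) {
    s <- predict_sensitivities(p, study_kinds, study_freqs)
    fit <- fit_dog(s, study_freqs)
    expect_lt(fit$sse, 1e-8)
    expect_equal(fit$peak_sf_analytic, peak_sf_analytic(p), tolerance = 0.02)
    expect_gt(fit$r_squared, 0.999)
    # invariant: analytic and DFT peaks agree within a bin; RF = 5 surround
    expect_lt(abs(fit$peak_sf_analytic - fit$peak_sf_dft), 1)
    expect_equal(fit$rf_extent_deg, 5 * fit$surround_sd_deg)
  }
})

test_that("flat sensitivity data yield near-zero correlation R-squared", {
  s <- matrix(5, 3, 4, dimnames = list(study_kinds, study_freqs))
  fit <- fit_dog(s, study_freqs)
  expect_lt(fit$r_squared, 0.05)
  expect_error(fit_dog(s * -1, study_freqs), class = "texmod_invalid_argument")
  expect_error(fit_dog(unname(s), study_freqs),
               class = "texmod_invalid_argument")
})

test_that("the scaled CVM variant fits CS and scales SQ and SN by 1/2 and 1/3", {
  p <- regime_params()$cvm
  cs <- predict_sensitivities(p, "CS", study_freqs)["CS", ]
  obs <- rbind(SN = cs / 3, SQ = cs / 2, CS = cs)
  fit <- fit_dog_cvm(obs, study_freqs)
  expect_equal(fit$scale_factors, c(CS = 1, SQ = 0.5, SN = 1 / 3))
  expect_equal(fit$predicted["SQ", ], 0.5 * fit$predicted["CS", ],
               tolerance = 1e-12, ignore_attr = TRUE)
  expect_equal(fit$predicted["SN", ], fit$predicted["CS", ] / 3,
               tolerance = 1e-12, ignore_attr = TRUE)
  expect_lt(fit$sse, 1e-8)
  expect_equal(fit$peak_sf_analytic, peak_sf_analytic(p), tolerance = 0.02)
  # halving the amplitude quarters the mean-square energy of the response
  expect_equal(mean(fit$predicted["SQ", ]^2), mean(fit$predicted["CS", ]^2) / 4)
  # vector input fits the CS row alone
  fit_v <- fit_dog_cvm(cs, study_freqs)
  expect_equal(fit_v$params$gamma, fit$params$gamma, tolerance = 1e-4)
})
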