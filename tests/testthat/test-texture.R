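test_that("envelope SD from octave bandwidth matches the rendered spectrum", {
  sigma <- gabor_sigma_from_bandwidth(6, 1.5)
  expect_equal(sigma, 0.065, tolerance = 0.01)
  # independent oracle: render a 1-D Gabor, measure the half-height
  # bandwidth of its amplitude spectrum
  span <- 4; n <- 2^14
  x <- seq(-span / 2, span / 2, length.out = n)
  g <- exp(-x^2 / (2 * sigma^2)) * sin(2 * pi * 6 * x)
  mags <- Mod(stats::fft(g))[seq_len(n / 2)]
  freqs <- (seq_len(n / 2) - 1) / span
  half <- max(mags) / 2
  above <- which(mags >= half)
  lo <- min(above); hi <- max(above)
  interp <- function(i, j) {
    freqs[i] + (half - mags[i]) * (freqs[j] - freqs[i]) / (mags[j] - mags[i])
  }
  f_lo <- interp(lo - 1, lo)
  f_hi <- interp(hi + 1, hi)
  expect_equal(log2(f_hi / f_lo), 1.5, tolerance = 0.01)
  # round trip through the inverse
  expect_equal(gabor_bandwidth_from_sigma(6, sigma), 1.5, tolerance = 1e-9)
  # wide-band limit of the closed form
  expect_equal(gabor_sigma_from_bandwidth(6, 40),
               sqrt(2 * log(2)) / (2 * pi * 6), tolerance = 1e-9)
  expect_error(gabor_sigma_from_bandwidth(-6, 1.5),
               class = "texmod_invalid_argument")
})

test_that("gabor placement respects the minimum-separation constraint", {
  set.seed(1)
  sigma <- gabor_params()$sigma
  pos <- place_gabors(2500, 1.7 * sigma, 10)
  expect_equal(nrow(pos), 2500)
  expect_true(all(sqrt(rowSums(pos^2)) <= 5))
  expect_gte(min(stats::dist(pos)), 1.7 * sigma)
  # reproducible for a fixed seed
  set.seed(1)
  expect_identical(place_gabors(2500, 1.7 * sigma, 10), pos)
  # single gabor
  set.seed(2)
  p1 <- place_gabors(1, 1, 10)
  expect_equal(nrow(p1), 1)
  expect_lte(sqrt(sum(p1^2)), 5)
  # infeasible density fails fast via the packing bound
  expect_error(place_gabors(10000, 1, 10),
               class = "texmod_infeasible_density")
})

test_that("orientation quantization maps onto the 1440-template grid", {
  expect_equal(quantize_orientation(0.13, 0.25), 0.25)
  expect_equal(quantize_orientation(90, 0.25), 90)
  expect_equal(quantize_orientation(-0.1, 0.25), 0)
  # nearest multiple of 359.9 is 360, which wraps to 0
  expect_equal(quantize_orientation(359.9, 0.25), 0)
  expect_equal(quantize_orientation(359.87, 0.25), 359.75, tolerance = 1e-9)
  sweep <- quantize_orientation(seq(0, 359.999, by = 0.01), 0.25)
  expect_equal(length(unique(sweep)), 1440)
})

test_that("modulation assignment implements the per-type rules", {
  set.seed(3)
  pos <- place_gabors(200, 0.05, 4)
  # zero amplitude: jitter-only baseline
  for (type in c("OM", "CM", "OVM")) {
    spec <- texture_spec(type, field_diameter = 4, n_gabors = 200)
    a <- assign_modulation(pos, spec, sample_waveform("SQ", 2, 0, 0))
    if (type == "CM") {
      expect_true(all(a$contrast == spec$mean_contrast))
    }
    jit <- spec$orientation_jitter
    expect_true(all(a$orientation %in%
                      quantize_orientation(c(90 - jit, 90 + jit), 0.25)))
  }
  # OM rule: orientation = 90 + j*5 + W(x), then grid-quantized
  spec <- texture_spec("OM", field_diameter = 4, n_gabors = 200)
  wave <- sample_waveform("SN", 1, 0.3, 20)
  set.seed(4)
  a <- assign_modulation(pos, spec, wave)
  w <- waveform_value(wave, (pos[, 1] + 2) / 4)
  resid_plus <- a$orientation - quantize_orientation(90 + 5 + w, 0.25)
  resid_minus <- a$orientation - quantize_orientation(90 - 5 + w, 0.25)
  expect_true(all(abs(resid_plus) < 1e-9 | abs(resid_minus) < 1e-9))
  # orientations land exactly on the grid
  expect_true(all(abs(a$orientation / 0.25 -
                        round(a$orientation / 0.25)) < 1e-9))
  # CM amplitude above mean contrast drives contrast negative: hard error
  spec_cm <- texture_spec("CM", field_diameter = 4, n_gabors = 200)
  expect_error(
    assign_modulation(pos, spec_cm, sample_waveform("SN", 1, 0, 0.5)),
    class = "texmod_out_of_range")
  # determinism under a fixed seed
  set.seed(9)
  a1 <- assign_modulation(pos, spec, wave)
  set.seed(9)
  a2 <- assign_modulation(pos, spec, wave)
  expect_identical(a1, a2)
})

test_that("variance-modulated types modulate spread, not mean", {
  set.seed(5)
  pos <- place_gabors(400, 0.04, 4)
  spec <- texture_spec("OVM", field_diameter = 4, n_gabors = 400)
  wave <- sample_waveform("SQ", 1, 0, 0.8)
  a <- assign_modulation(pos, spec, wave)
  w <- waveform_value(wave, (pos[, 1] + 2) / 4)
  spread <- abs(a$orientation - 90)
  # |orientation - mean| = j0 * (1 + W(x)) up to grid rounding (0.125 deg)
  expect_lt(max(abs(spread - spec$orientation_jitter * (1 + w))), 0.13)
  # CVM: contrasts symmetric about the mean with modulated spread
  spec_cv <- texture_spec("CVM", field_diameter = 4, n_gabors = 400)
  a_cv <- assign_modulation(pos, spec_cv, wave)
  expect_equal(abs(a_cv$contrast - spec_cv$mean_contrast),
               spec_cv$contrast_jitter * (1 + w), tolerance = 1e-9)
})

test_that("rendering composites Gabors on a mid-grey background", {
  spec <- small_spec("OM")
  wave <- sample_waveform("SN", 2, 0, 10)
  # empty assignment list: uniform background at 0.5
  empty <- assign_modulation(matrix(numeric(0), 0, 2), spec, wave)
  img0 <- render_texture(spec, empty, resolution = 16)
  expect_true(all(img0 == 0.5))
  set.seed(6)
  tex <- synthesize_texture(spec, wave, resolution = 32)
  expect_true(all(tex$image >= 0 & tex$image <= 1))
  # odd-symmetric micropatterns leave the mean luminance near background
  expect_lt(abs(mean(tex$image) - 0.5), 0.005)
  expect_error(render_texture(spec, tex$assignments, resolution = 4),
               class = "texmod_invalid_argument")
})

test_that("LM frame profiles give 3:1 peak-to-trough ratios at study settings", {
  wave <- sample_waveform("SQ", 1, 0, 0.5)
  frames <- lm_frame_profiles(wave)
  expect_equal(max(frames$grating_luminance) / min(frames$grating_luminance), 3)
  expect_equal(max(frames$texture_contrast) / min(frames$texture_contrast), 3)
  # contrast amplitude 0.333 about mean 0.666
  expect_equal(mean(range(frames$texture_contrast)), 0.666)
  expect_equal(diff(range(frames$texture_contrast)) / 2, 0.333)
  expect_error(lm_frame_profiles(sample_waveform("SQ", 1, 0, 0.7)),
               class = "texmod_out_of_range")
  # rendered LM texture averages the two frames
  spec <- small_spec("LM", n_gabors = 20)
  set.seed(7)
  tex <- synthesize_texture(spec, wave, resolution = 32)
  expect_true(all(tex$image >= 0 & tex$image <= 1))
})
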