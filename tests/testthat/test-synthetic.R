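test_that("the factorial grid has the study's condition and group counts", {
  grid <- generate_condition_grid(study_design())
  expect_equal(sum(grid$task == "detection"), 60)
  expect_equal(sum(grid$task == "discrimination"), 60)
  # fit groups: texture x task x participant
  d <- study_design()
  expect_equal(length(d$texture_types) * length(d$tasks) * d$n_participants, 30)
  tiny <- study_design(texture_types = "OM", waveforms = "SN",
                       frequencies = 2, tasks = "detection")
  expect_equal(nrow(generate_condition_grid(tiny)), 1)
})

test_that("noise-free thresholds equal reciprocal model sensitivities", {
  sc <- noise_free_scenario(seed = 2)
  d <- small_design()
  recs <- generate_thresholds(sc, d)
  expect_equal(nrow(recs),
               2 * 2 * 3 * 4 * d$n_participants)  # textures x tasks x wf x f x pp
  p_det <- regime_params()$detection
  s <- predict_sensitivities(p_det, d$waveforms, d$frequencies)
  sub <- recs[recs$task == "detection" & recs$texture_type == "OM", ]
  expect_equal(sub$threshold,
               1 / s[cbind(sub$waveform, as.character(sub$frequency_cpi))],
               tolerance = 1e-12, ignore_attr = TRUE)
  expect_true(all(recs$n_staircases == d$thresholds_per_condition))
  # same seed reproduces the table exactly
  expect_identical(generate_thresholds(noise_free_scenario(seed = 2), d), recs)
})

test_that("detection-regime thresholds follow SQ < SN < CS at every frequency", {
  recs <- generate_thresholds(generator_scenario(seed = 4), study_design())
  det <- recs[recs$task == "detection" & recs$texture_type != "CVM", ]
  agg <- stats::aggregate(threshold ~ texture_type + waveform + frequency_cpi,
                          det, mean)
  for (tt in unique(agg$texture_type)) {
    for (f in unique(agg$frequency_cpi)) {
      cell <- agg[agg$texture_type == tt & agg$frequency_cpi == f, ]
      thr <- stats::setNames(cell$threshold, cell$waveform)
      expect_lt(thr[["SQ"]], thr[["SN"]])
      expect_lt(thr[["SN"]], thr[["CS"]])
    }
  }
})

test_that("CVM scaling makes the sensitivity rows proportional 1 : 1/2 : 1/3", {
  sc <- noise_free_scenario(seed = 5)
  d <- study_design(texture_types = "CVM", n_participants = 1)
  recs <- generate_thresholds(sc, d)
  s <- thresholds_to_sensitivities(recs)[[1]]
  expect_equal(s["SQ", ], s["CS", ] / 2, tolerance = 1e-9)
  expect_equal(s["SN", ], s["CS", ] / 3, tolerance = 1e-9)
})

test_that("refitting noise-free generated data recovers the generating peak", {
  sc <- noise_free_scenario(seed = 6)
  d <- study_design(n_participants = 1)
  recs <- generate_thresholds(sc, d)
  groups <- thresholds_to_sensitivities(recs)
  for (label in c("S1.OM.detection", "S1.OM.discrimination")) {
    m <- groups[[label]]
    truth <- peak_sf_analytic(
      regime_params()[[attr(m, "task")]])
    fit <- fit_dog(m, attr(m, "frequencies"))
    expect_equal(fit$peak_sf_analytic, truth, tolerance = 0.02)
  }
})

test_that("undefined-peak generating parameters are rejected", {
  tp <- default_true_params()
  tp$delta <- 0.9
  sc <- generator_scenario(true_params = tp, seed = 1)
  expect_error(generate_thresholds(sc, small_design()),
               class = "texmod_invalid_scenario")
})

test_that("staircase-based generation tracks the model thresholds", {
  d <- study_design(texture_types = "OM", tasks = "detection",
                    n_participants = 1, thresholds_per_condition = 3)
  sc <- generator_scenario(noise_cv = 0, observer_slope = 8, seed = 7)
  recs <- generate_via_staircase(sc, d)
  expect_equal(nrow(recs), 12)
  expect_true(all(is.finite(recs$se)))
  expect_true(all(recs$n_staircases == 3))
  s <- predict_sensitivities(regime_params()$detection, d$waveforms,
                             d$frequencies)
  rel_err <- abs(recs$threshold *
                   s[cbind(recs$waveform, as.character(recs$frequency_cpi))] - 1)
  # high-slope observers: staircase thresholds near reciprocal sensitivities
  expect_lt(median(rel_err), 0.1)
})

test_that("threshold tables round-trip through CSV", {
  recs <- generate_thresholds(noise_free_scenario(1), small_design())
  path <- withr::local_tempfile(fileext = ".csv")
  write_thresholds_csv(recs, path)
  back <- read_thresholds_csv(path)
  expect_equal(back$threshold, recs$threshold)
  expect_error(read_thresholds_csv(write_waveform_csv(
    sample_waveform("SN", 1), withr::local_tempfile(fileext = ".csv"))),
    class = "texmod_invalid_argument")
})
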