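test_that("planar-wave geometry delivers the wavefront in the right order", {
  fs <- 20
  # south-bound wave: both top electrodes simultaneous, bottom 0.7 s later
  rec <- simulate_record(wave_spec(cv = 10, phi = 0, onset_s = 15,
                                   carrier_hz = 1.0, burst_sd_s = 1),
                         duration_s = 30, gains = c(1, 1, 1, 1))
  delay <- function(a, b) raw_xcorr_peak(rec$signals[[a]], rec$signals[[b]],
                                         max_lag = 30)
  expect_equal(delay("E2", "E1"), 0L)
  expect_equal(delay("E2", "E3"), -14L)  # E3 receives 14 samples later
  expect_equal(delay("E1", "E4"), -14L)
  # east-bound wave: left column first, right column 0.7 s later
  rec2 <- simulate_record(wave_spec(cv = 10, phi = 90, onset_s = 15,
                                    carrier_hz = 1.0, burst_sd_s = 1),
                          duration_s = 30, gains = c(1, 1, 1, 1))
  delay2 <- function(a, b) raw_xcorr_peak(rec2$signals[[a]], rec2$signals[[b]],
                                          max_lag = 30)
  expect_equal(delay2("E2", "E3"), 0L)
  expect_equal(delay2("E2", "E1"), -14L)
  expect_equal(delay2("E3", "E4"), -14L)
})

test_that("bipolar identities hold exactly, with and without noise", {
  rec <- simulate_record(wave_spec(cv = 8, phi = -50, onset_s = 15),
                         duration_s = 40, noise_sd = 3, seed = 21)
  s <- rec$signals
  expect_identical(s$S1, s$E2 - s$E1)
  expect_identical(s$S2, s$E2 - s$E3)
  expect_identical(s$S3, s$E4 - s$E3)
  expect_equal(derive_s4(s$S1, s$S2, s$S3), s$E4 - s$E1)
})

test_that("overlapping waves are refused and annotations cover each wave", {
  expect_error(simulate_record(list(wave_spec(onset_s = 15),
                                    wave_spec(onset_s = 18)),
                               duration_s = 60),
               "overlap")
  waves <- list(wave_spec(cv = 10, phi = 10, onset_s = 20),
                wave_spec(cv = 12, phi = 100, onset_s = 80))
  rec <- simulate_record(waves, duration_s = 140)
  ann <- rec$annotations
  expect_equal(sum(ann$kind == "contraction"), 2L)
  for (w in waves) {
    hit <- ann$kind == "contraction" &
      ann$start <= w$onset_s * rec$fs & ann$end >= w$onset_s * rec$fs
    expect_true(any(hit))
  }
  expect_gte(sum(ann$kind == "dummy"), 1L)
})

test_that("the noise-free sweep recovers sector and velocity everywhere feasible", {
  cvs <- c(8, 10, 15, 20)
  phis <- c(0, 30, -60, 90, 120, -150, 179)
  fs <- 20; d <- 7
  for (cv in cvs) for (phi in phis) {
    # geometric feasibility: both axis lags inside the +-1 s search range
    if (d * abs(cos(phi * pi / 180)) > cv ||
        d * abs(sin(phi * pi / 180)) > cv) next
    w <- wave_spec(cv = cv, phi = phi, onset_s = 15)
    rw <- recover_wave(ehg_track(simulate_record(w, duration_s = 30),
                                 band = "B1"), w)
    expect_equal(rw$sector, true_sector(phi)$sector,
                 label = sprintf("sector at cv=%g phi=%g", cv, phi))
    bound <- (abs(cos(phi * pi / 180)) + abs(sin(phi * pi / 180))) / (fs * d)
    expect_lte(abs(1 / rw$cv - 1 / cv), bound + 1e-12)
  }
})

test_that("sector accuracy does not improve as noise grows", {
  waves <- expand.grid(cv = c(10, 15), phi = c(20, 70, -110, 160))
  acc <- vapply(c(0, 4, 40), function(ns) {
    hits <- mapply(function(cv, phi) {
      w <- wave_spec(cv = cv, phi = phi, onset_s = 15)
      rec <- simulate_record(w, duration_s = 30, noise_sd = ns,
                             seed = 100 + round(ns))
      rw <- recover_wave(ehg_track(rec, band = "B1"), w)
      !is.na(rw$sector) && rw$sector == true_sector(phi)$sector
    }, waves$cv, waves$phi)
    mean(hits)
  }, numeric(1))
  expect_equal(acc[1], 1)
  expect_true(acc[3] <= acc[1])
})

test_that("feature cohorts express the requested class effect", {
  # null cohort: chance-level classification
  null_cohort <- simulate_feature_cohort(effect = cohort_effect(delta = 0),
                                         seed = 5)
  rep0 <- qda_cv(null_cohort$x, null_cohort$y, positive = "preterm",
                 seed = 5, n_reps = 10)
  expect_gte(rep0$CA, 35)
  expect_lte(rep0$CA, 65)
  # single-feature effect: that feature separates, null features mostly not
  eff <- cohort_effect(delta = 0)
  eff$mu["preterm", "SE_S2"] <- eff$mu["term", "SE_S2"] - 0.5
  coh <- simulate_feature_cohort(effect = eff, seed = 6)
  p_eff <- pooled_t_test(coh$x[coh$y == "preterm", "SE_S2"],
                         coh$x[coh$y == "term", "SE_S2"])
  p_null <- pooled_t_test(coh$x[coh$y == "preterm", "P_V"],
                          coh$x[coh$y == "term", "P_V"])
  expect_lt(p_eff, 0.01)
  expect_gt(p_null, 0.01)
  # cohort sizes mirror the study: 47 + 53, balanced by SMOTE to 53 + 53
  expect_equal(as.vector(table(coh$y)), c(47, 53))
  bal <- smote_balance(coh$x[coh$y == "preterm", ],
                       coh$x[coh$y == "term", ])
  expect_equal(as.vector(table(bal$y)), c(53, 53))
  # invalid covariance is refused
  eff_bad <- cohort_effect()
  eff_bad$sigma$preterm <- matrix(c(1, 2, 0, 2, 1, 0, 0, 0, 1), 3)
  expect_error(simulate_feature_cohort(effect = eff_bad), "positive definite")
})
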