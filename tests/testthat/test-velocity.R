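test_that("window normalization maps to [0, 1] and flags constant windows", {
  expect_equal(window_normalize(c(2, 4, 6)), c(0, 0.5, 1))
  expect_null(window_normalize(c(5, 5, 5)))
  expect_error(window_normalize(numeric(0)), "empty")
  # invariance under positive affine transforms
  set.seed(5)
  for (i in 1:20) {
    x <- rnorm(50)
    a <- runif(1, 0.1, 10); b <- runif(1, -5, 5)
    expect_equal(window_normalize(a * x + b), window_normalize(x))
  }
})

test_that("similarity shift equals the brute-force lag search", {
  set.seed(21)
  for (i in 1:150) {
    n <- sample(40:120, 1)
    L <- sample(5:20, 1)
    x <- window_normalize(rnorm(n))
    y <- window_normalize(rnorm(n))
    expect_identical(similarity_shift(x, y, L), brute_shift(x, y, L))
  }
})

test_that("similarity shift sign convention and range clamp", {
  set.seed(31)
  base <- ehg_bandpass(rnorm(300), 20, "Bb")  # broadband, sharp autocorrelation
  x <- window_normalize(base[21:120])
  y_delayed <- window_normalize(base[15:114])  # y is x delayed by 6 samples
  # Eq.-1 convention: a delayed copy maximizes C at minus the delay
  expect_identical(similarity_shift(x, y_delayed, 20), -6L)
  y_leading <- window_normalize(base[27:126])
  expect_identical(similarity_shift(x, y_leading, 20), 6L)
  expect_identical(similarity_shift(x, x, 20), 0L)
  # true delay outside the searched range: result stays clamped
  far <- window_normalize(base[1:100])
  s <- similarity_shift(window_normalize(base[31:130]), far, 20)
  expect_lte(abs(s), 20L)
  # degenerate windows yield no shift
  expect_true(is.na(similarity_shift(NULL, x, 20)))
  expect_true(is.na(similarity_shift(x, window_normalize(rep(1, 100)), 20)))
})

test_that("correlation ties break toward small then negative lags", {
  # constant windows (bypassing normalization): every lag ties -> lag 0
  expect_identical(similarity_shift(rep(1, 5), rep(1, 5), 2), 0L)
  # palindromic window autocorrelation ties exactly at +-m; here the scaled
  # correlation peaks at +-1 (4 > 19/5), so the negative lag must win
  pal <- c(1, 2, 3, 2, 1)
  expect_identical(similarity_shift(pal, pal, 2), -1L)
})

test_that("shift-to-velocity closed forms, outliers and no-propagation", {
  # vertical-only: t_V = 0.7 s -> CV = 10 cm/s, phi = 0 (south)
  v <- shifts_to_velocity(-14, 0, 20, 7, 30)
  expect_equal(v$t_v, 0.7)
  expect_equal(v$cv, 10)
  expect_equal(v$phi, 0)
  expect_equal(assign_sector(v$phi)$sector, "south")
  # diagonal: t_V = t_H = 0.35 s -> CV = 7/(0.35*sqrt(2)), phi = 45 (east)
  v <- shifts_to_velocity(-7, -7, 20, 7, 30)
  expect_equal(v$cv, 7 / (0.35 * sqrt(2)))
  expect_equal(v$phi, 45)
  expect_equal(assign_sector(v$phi)$direction, "horizontal")
  expect_equal(assign_sector(v$phi)$sector, "east")
  # both shifts zero: no propagation
  v <- shifts_to_velocity(0, 0, 20, 7, 30)
  expect_equal(v$cv, 0)
  expect_true(is.na(v$phi))
  # one-sample shift: 140 cm/s exceeds the 30 cm/s ceiling -> zeroed
  v <- shifts_to_velocity(-1, 0, 20, 7, 30)
  expect_equal(v$cv, 0)
  expect_true(is.na(v$phi))
  # degenerate shift propagates to no-propagation
  v <- shifts_to_velocity(NA, 0, 20, 7, 30)
  expect_equal(v$cv, 0)
})

test_that("nonzero velocities respect the geometric floor and ceiling", {
  for (sv in -20:20) for (sh in c(-20, -7, -3, 0, 3, 11, 20)) {
    v <- shifts_to_velocity(sv, sh, 20, 7, 30)
    if (v$cv != 0) {
      expect_gte(v$cv, 7 / (sqrt(2) * 1.0) - 1e-9)
      expect_lte(v$cv, 30)
      expect_false(is.na(v$phi))
      expect_true(v$phi >= -180 && v$phi < 180)
    } else {
      expect_true(is.na(v$phi))
    }
  }
})

test_that("sector alignment follows the half-open compass rules", {
  expect_equal(assign_sector(0), list(direction = "vertical", sector = "south"))
  expect_equal(assign_sector(-45)$sector, "south")   # -45 belongs to rule 1
  expect_equal(assign_sector(45)$sector, "east")
  expect_equal(assign_sector(135)$sector, "north")
  expect_equal(assign_sector(-135)$sector, "west")
  expect_equal(assign_sector(-46)$sector, "west")
  expect_equal(assign_sector(179.9)$sector, "north")
  expect_equal(assign_sector(-180)$sector, "north")
  expect_equal(assign_sector(NA)$direction, NA_character_)
  expect_error(assign_sector(200), "180")
  # direction/sector coupling over a grid of angles
  for (phi in seq(-180, 179, by = 7.3)) {
    ds <- assign_sector(phi)
    if (ds$direction == "vertical") expect_true(ds$sector %in% c("south", "north"))
    else expect_true(ds$sector %in% c("east", "west"))
  }
})

test_that("tracking tiles a 30-minute record into 3591 correlation intervals", {
  n <- 36000
  zero <- orient_signals(numeric(n), numeric(n), numeric(n), numeric(n),
                         "B1", 20)
  tr <- ehg_track(zero)
  expect_equal(nrow(tr$estimates), 3591L)
  expect_equal(diff(tr$estimates$center_sample)[1], 10)
  # all-zero record: every estimate is no-propagation
  expect_true(all(tr$estimates$cv == 0))
  expect_true(all(is.na(tr$estimates$phi)))
  expect_true(all(is.na(tr$estimates$sector)))
})

test_that("records shorter than the window are refused", {
  short <- orient_signals(numeric(50), numeric(50), numeric(50), numeric(50),
                          "B1", 20)
  expect_error(ehg_track(short), "shorter than")
})

test_that("a single synthetic planar wave is recovered with its sector", {
  w <- wave_spec(cv = 10, phi = 0, onset_s = 15)
  rec <- simulate_record(w, duration_s = 30)
  tr <- ehg_track(rec, band = "B1")
  rw <- recover_wave(tr, w)
  expect_equal(rw$sector, "south")
  expect_lte(abs(1 / rw$cv - 1 / 10), (1 / 20) * 1 / 7 + 1e-12)
  # shift bound holds throughout
  e <- tr$estimates
  expect_true(all(abs(e$s_v) <= 20, na.rm = TRUE))
  expect_true(all(abs(e$s_h) <= 20, na.rm = TRUE))
})

test_that("rotating a wave by 90 degrees swaps the shift roles", {
  w1 <- wave_spec(cv = 10, phi = 30, onset_s = 15)
  w2 <- wave_spec(cv = 10, phi = 120, onset_s = 15)
  e1 <- ehg_track(simulate_record(w1, duration_s = 30), band = "B1")$estimates
  e2 <- ehg_track(simulate_record(w2, duration_s = 30), band = "B1")$estimates
  mid <- abs(e1$center_sample / 20 - 15) <= 1.5
  med <- function(x) stats::median(x, na.rm = TRUE)
  # (s_v, s_h)(phi + 90) = (-s_h, s_v)(phi), within one sample of quantization
  expect_lte(abs(med(e2$s_v[mid]) - (-med(e1$s_h[mid]))), 1)
  expect_lte(abs(med(e2$s_h[mid]) - med(e1$s_v[mid])), 1)
})

test_that("track CSV serialization has the documented columns", {
  w <- wave_spec(cv = 12, phi = 60, onset_s = 15)
  tr <- ehg_track(simulate_record(w, duration_s = 30), band = "B1")
  path <- withr::local_tempfile(fileext = ".csv")
  write_track_csv(tr, path)
  csv <- utils::read.csv(path)
  expect_identical(names(csv), c("k", "center_s", "s_V", "s_H", "t_V", "t_H",
                                 "CV_cm_s", "phi_deg", "direction", "sector"))
  expect_equal(nrow(csv), nrow(tr$estimates))
})

test_that("invalid estimator parameters are refused", {
  expect_error(xcorr_params(w_c = 2, d_ss = 1), "exceed")
  expect_error(xcorr_params(d_ci = 0), "> 0")
  expect_error(xcorr_params(cv_max = -5), "> 0")
})
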