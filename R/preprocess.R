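#' Frequency band table
#'
#' Canonical analysis bands for uterine EHG signals at 20 Hz sampling.
#' `B0p` (0.3-1.0 Hz) covers the contraction-related activity, `Bb`
#' (0.3-4.0 Hz) the broad burst content, and `B1`-`B3` (1.0-2.2, 2.2-3.5,
#' 3.5-5.0 Hz) the region above 1 Hz where the maternal heart rate and its
#' harmonics influence the uterus. `wide` (0.08-5.0 Hz) is the acquisition-wide
#' band applied before the fourth bipolar signal is derived.
#'
#' @return data frame with columns `name`, `f_low`, `f_high` (Hz).
#' @export
ehg_bands <- function() {
  data.frame(
    name = c("B0p", "Bb", "B1", "B2", "B3", "wide"),
    f_low = c(0.3, 0.3, 1.0, 2.2, 3.5, 0.08),
    f_high = c(1.0, 4.0, 2.2, 3.5, 5.0, 5.0),
    stringsAsFactors = FALSE)
}

#' Band specification
#'
#' @param name a band name from [ehg_bands()], or `"custom"` with explicit
#'   edges.
#' @param f_low,f_high band edges in Hz (only for `name = "custom"`).
#' @return object of class `ehg_band` with fields `name`, `f_low`, `f_high`.
#' @export
band_spec <- function(name, f_low = NULL, f_high = NULL) {
  tab <- ehg_bands()
  if (name %in% tab$name) {
    row <- tab[tab$name == name, ]
    f_low <- row$f_low; f_high <- row$f_high
  } else {
    assert_that(identical(name, "custom") && !is.null(f_low) && !is.null(f_high),
                "unknown band '", name, "'; use one of ",
                paste(tab$name, collapse = ", "), " or 'custom'")
  }
  assert_that(f_low > 0 && f_low < f_high, "band requires 0 < f_low < f_high",
              class = "ehg_parameter_error")
  structure(list(name = name, f_low = f_low, f_high = f_high),
            class = "ehg_band")
}

as_band <- function(band) {
  if (inherits(band, "ehg_band")) band else band_spec(band)
}

#' @export
print.ehg_band <- function(x, ...) {
  cat(sprintf("<ehg_band> %s: %.2f-%.2f Hz\n", x$name, x$f_low, x$f_high))
  invisible(x)
}

#' Derive the fourth bipolar signal
#'
#' The square electrode montage records S1 = E2-E1 (top pair), S2 = E2-E3
#' (left pair) and S3 = E4-E3 (bottom pair). The missing right-pair signal
#' follows from the electrode potentials as S4 = E4-E1 = S1 - S2 + S3,
#' computed elementwise. Inputs are expected on the wide (0.08-5.0 Hz) band.
#'
#' @param s1,s2,s3 equal-length numeric vectors.
#' @return numeric vector S4.
#' @export
derive_s4 <- function(s1, s2, s3) {
  assert_that(length(s1) == length(s2) && length(s2) == length(s3),
              "S1, S2, S3 must have equal length", class = "ehg_structural_error")
  s1 - s2 + s3
}

#' Zero-phase Butterworth band-pass filter
#'
#' A fourth-order Butterworth band-pass design (four poles per edge, following
#' the convention of `butter(4, [low high])`, whose bidirectional application
#' rolls off at 160 dB per decade) applied forward and backward for zero phase
#' shift. Edge transients are controlled by odd-reflection padding of length
#' `3 * (order + 1)` samples on both ends together with steady-state filter
#' initialization at the padded signal's first value.
#'
#' @param x numeric signal.
#' @param fs sampling frequency in Hz.
#' @param band an `ehg_band` or band name.
#' @return filtered signal, same length as `x`.
#' @export
ehg_bandpass <- function(x, fs, band) {
  band <- as_band(band)
  assert_that(band$f_high < fs / 2,
              sprintf("band %s invalid at fs = %g Hz (f_high must be < fs/2)",
                      band$name, fs), class = "ehg_parameter_error")
  bf <- signal::butter(4, c(band$f_low, band$f_high) / (fs / 2), type = "pass")
  filtfilt_reflect(bf$b, bf$a, x)
}

# Forward-backward IIR filtering with odd-reflection end padding and
# steady-state initial conditions (previous inputs at the first padded value,
# previous outputs at its DC response), as in conventional filtfilt
# implementations.
filtfilt_reflect <- function(b, a, x) {
  nord <- max(length(a), length(b)) - 1L
  pad <- 3L * (nord + 1L)
  n <- length(x)
  assert_that(n > pad, "signal too short for filter warm-up (need > ",
              pad, " samples)", class = "ehg_parameter_error")
  h1 <- sum(b) / sum(a)
  pass <- function(z) {
    as.numeric(signal::filter(b, a, z,
                              init = rep(z[1] * h1, length(a) - 1L),
                              init.x = rep(z[1], length(b) - 1L)))
  }
  ext <- c(2 * x[1] - x[(pad + 1L):2L], x, 2 * x[n] - x[(n - 1L):(n - pad)])
  y <- pass(ext)
  y <- rev(pass(rev(y)))
  y[(pad + 1L):(pad + n)]
}

#' Orient the four bipolar signals consistently
#'
#' For a valid cross-correlation between the members of the upper/lower pair
#' (S1, S3) and the left/right pair (S2, S4), the paired signals must share
#' polarity; the montage wiring requires flipping S3 and S4 by -1. The
#' returned set records that the flip has been applied; orienting twice is an
#' error.
#'
#' @param s1,s2,s3,s4 equal-length band-filtered signals (S4 already derived
#'   on the wide band).
#' @param band the band the signals are filtered to.
#' @param fs sampling frequency in Hz.
#' @return object of class `ehg_oriented` with fields `S1`..`S4`, `band`, `fs`.
#' @export
orient_signals <- function(s1, s2, s3, s4, band, fs) {
  if (inherits(s1, "ehg_oriented"))
    stop_ehg("signals are already oriented", class = "ehg_state_error")
  assert_that(length(unique(c(length(s1), length(s2), length(s3), length(s4)))) == 1L,
              "all four signals must have equal length", class = "ehg_structural_error")
  structure(list(S1 = s1, S2 = s2, S3 = -s3, S4 = -s4,
                 band = as_band(band), fs = fs, oriented = TRUE),
            class = "ehg_oriented")
}

#' @export
print.ehg_oriented <- function(x, ...) {
  cat(sprintf("<ehg_oriented> %d samples at %g Hz, band %s (%.2f-%.2f Hz)\n",
              length(x$S1), x$fs, x$band$name, x$band$f_low, x$band$f_high))
  invisible(x)
}

#' Preprocess a record for one analysis band
#'
#' Fixed pipeline: wide-band (0.08-5.0 Hz) zero-phase filtering of S1-S3,
#' derivation of S4 on the wide band, per-band filtering of all four signals,
#' then polarity orientation of S3/S4.
#'
#' @param record an [ehg_record()] with channels S1, S2, S3.
#' @param band target band, an `ehg_band` or name from [ehg_bands()].
#' @return an `ehg_oriented` signal set.
#' @export
preprocess_record <- function(record, band) {
  assert_that(inherits(record, "ehg_record"), "record must be an ehg_record")
  assert_that(all(c("S1", "S2", "S3") %in% names(record$signals)),
              "record must provide channels S1, S2, S3",
              class = "ehg_structural_error")
  band <- as_band(band)
  fs <- record$fs
  wide <- band_spec("wide")
  w1 <- ehg_bandpass(record$signals$S1, fs, wide)
  w2 <- ehg_bandpass(record$signals$S2, fs, wide)
  w3 <- ehg_bandpass(record$signals$S3, fs, wide)
  w4 <- derive_s4(w1, w2, w3)
  b1 <- ehg_bandpass(w1, fs, band)
  b2 <- ehg_bandpass(w2, fs, band)
  b3 <- ehg_bandpass(w3, fs, band)
  b4 <- ehg_bandpass(w4, fs, band)
  orient_signals(b1, b2, b3, b4, band, fs)
}
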