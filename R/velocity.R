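#' Short-time cross-correlation parameters
#'
#' Parameters of the velocity estimator: `w_c` is the correlation window
#' length in seconds, `d_ci` the spacing of consecutive correlation intervals,
#' `d_ss` the maximum searched similarity shift (seconds, both directions),
#' `d_cm` the inter-electrode spacing of the square montage in centimetres and
#' `cv_max` the physiological ceiling above which a velocity estimate is
#' treated as an outlier. Defaults are the study settings: 5 s window, 0.5 s
#' step, +/-1 s search, 7 cm spacing, 30 cm/s ceiling.
#'
#' @param w_c correlation window length (s); must exceed `2 * d_ss`.
#' @param d_ci correlation-interval spacing (s).
#' @param d_ss maximum searched shift (s).
#' @param d_cm electrode spacing (cm).
#' @param cv_max outlier ceiling (cm/s).
#' @return object of class `xcorr_params`.
#' @export
xcorr_params <- function(w_c = 5, d_ci = 0.5, d_ss = 1, d_cm = 7, cv_max = 30) {
  assert_that(w_c > 2 * d_ss, "w_c must exceed 2 * d_ss",
              class = "ehg_parameter_error")
  assert_that(d_ci > 0 && d_ss > 0 && d_cm > 0 && cv_max > 0,
              "d_ci, d_ss, d_cm, cv_max must be > 0",
              class = "ehg_parameter_error")
  structure(list(w_c = w_c, d_ci = d_ci, d_ss = d_ss, d_cm = d_cm,
                 cv_max = cv_max), class = "xcorr_params")
}

#' Min-max normalization of a correlation window
#'
#' Rescales a window to `[0, 1]` as `(x - min(x)) / max(x - min(x))`.
#' A constant window has no range and is degenerate: `NULL` is returned and
#' the caller treats the window as carrying no propagation information.
#'
#' @param x non-empty numeric window.
#' @return normalized vector, or `NULL` for a degenerate (constant) window.
#' @export
window_normalize <- function(x) {
  assert_that(length(x) > 0L, "empty window")
  rng <- max(x) - min(x)
  if (rng == 0) return(NULL)
  (x - min(x)) / rng
}

#' Similarity shift between two normalized windows
#'
#' Evaluates the cross-correlation `C(m) = sum_n x(n) * y(n - m)` over integer
#' lags `m` in `[-max_lag, max_lag]` and returns the lag maximizing it. Under
#' this summation convention a positive shift means `y` leads `x`. Inside a
#' finite window only `N - |m|` products exist at lag `m`; the sum is therefore
#' scaled by `1 / (N - |m|)` (the unbiased finite-sample estimate of the
#' correlation) so that all searched lags compete on equal overlap --- on the
#' non-negative min-max-normalized windows the raw truncated sum would
#' otherwise be biased toward zero lag regardless of the signal content. Ties
#' at the maximum are broken toward the smallest `|m|`, then toward negative
#' `m`, biasing ambiguous windows toward "no propagation" rather than spurious
#' fast waves.
#'
#' @param x,y equal-length normalized windows ([window_normalize()]); `NULL`
#'   (degenerate) inputs yield `NA`.
#' @param max_lag maximum searched lag in samples (20 at the defaults).
#' @return integer shift, or `NA` when either window is degenerate.
#' @export
similarity_shift <- function(x, y, max_lag) {
  if (is.null(x) || is.null(y)) return(NA_integer_)
  assert_that(length(x) == length(y), "windows must have equal length",
              class = "ehg_structural_error")
  n <- length(x)
  assert_that(max_lag < n, "max_lag must be smaller than the window length",
              class = "ehg_parameter_error")
  lags <- -max_lag:max_lag
  cc <- vapply(lags, function(m) {
    s <- if (m >= 0) sum(x[(1L + m):n] * y[1L:(n - m)])
         else sum(x[1L:(n + m)] * y[(1L - m):n])
    s / (n - abs(m))
  }, numeric(1))
  ord <- order(abs(lags), lags)
  best <- ord[which.max(cc[ord])]
  as.integer(lags[best])
}

#' Convert similarity shifts to a velocity estimate
#'
#' Transitional times follow from the shifts as `t = -s / fs`; the
#' conduction-velocity amplitude of the assumed planar wave is
#' `CV = d / sqrt(t_V^2 + t_H^2)` and the incidence angle the four-quadrant
#' arctangent of `t_H / t_V`, measured from the vertical axis in degrees in
#' `[-180, 180)`. Two cases collapse to "no propagation" (`CV = 0`, angle
#' undefined): both transitional times zero, and `CV` above the outlier
#' ceiling `cv_max` (transitional times too short to be physiological).
#' A degenerate (`NA`) shift likewise yields no propagation.
#'
#' @param s_v,s_h vertical and horizontal similarity shifts in samples.
#' @param fs sampling frequency (Hz).
#' @param d electrode spacing (cm).
#' @param cv_max outlier ceiling (cm/s).
#' @return list with `t_v`, `t_h` (s), `cv` (cm/s, 0 for no propagation) and
#'   `phi` (degrees, `NA` when `cv` is 0).
#' @export
shifts_to_velocity <- function(s_v, s_h, fs, d, cv_max) {
  assert_that(fs > 0 && d > 0 && cv_max > 0, "fs, d, cv_max must be > 0",
              class = "ehg_parameter_error")
  if (is.na(s_v) || is.na(s_h))
    return(list(t_v = NA_real_, t_h = NA_real_, cv = 0, phi = NA_real_))
  t_v <- -s_v / fs
  t_h <- -s_h / fs
  if (t_v == 0 && t_h == 0)
    return(list(t_v = t_v, t_h = t_h, cv = 0, phi = NA_real_))
  cv <- d / sqrt(t_v^2 + t_h^2)
  if (cv > cv_max)
    return(list(t_v = t_v, t_h = t_h, cv = 0, phi = NA_real_))
  phi <- atan2(t_h, t_v) * 180 / pi
  if (phi >= 180) phi <- phi - 360
  if (phi == 0) phi <- 0  # normalize negative zero
  list(t_v = t_v + 0, t_h = t_h + 0, cv = cv, phi = phi)
}

#' Align an incidence angle to a direction and sector
#'
#' Half-open alignment rules on the abdominal-wall compass:
#' `[-45, 45)` vertical/south, `[45, 135)` horizontal/east, `[135, 180)` and
#' `[-180, -135)` vertical/north, `[-135, -45)` horizontal/west. An undefined
#' angle yields undefined direction and sector.
#'
#' @param phi incidence angle in degrees in `[-180, 180)`, or `NA`.
#' @return list with `direction` and `sector` strings (`NA` when undefined).
#' @export
assign_sector <- function(phi) {
  if (is.na(phi))
    return(list(direction = NA_character_, sector = NA_character_))
  assert_that(phi >= -180 && phi < 180, "phi must lie in [-180, 180)",
              class = "ehg_parameter_error")
  if (phi >= -45 && phi < 45) list(direction = "vertical", sector = "south")
  else if (phi >= 45 && phi < 135) list(direction = "horizontal", sector = "east")
  else if (phi >= 135 || phi < -135) list(direction = "vertical", sector = "north")
  else list(direction = "horizontal", sector = "west")
}

#' Track conduction velocity over a record
#'
#' The core estimator. Correlation-interval centers are tiled every `d_ci`
#' seconds starting at `w_c / 2`; at each center a `w_c`-second window is cut
#' from the upper/lower pair (S1, S3) and the left/right pair (S2, S4), each
#' window min-max normalized, the similarity shifts searched over
#' `+/- d_ss` seconds independently per pair, and the shifts converted to a
#' conduction-velocity amplitude, incidence angle, direction and sector.
#' Windows that would overrun a record edge are omitted (no zero padding,
#' which would bias shifts toward zero).
#'
#' @param x an [ehg_record()] (preprocessed internally via
#'   [preprocess_record()]) or an `ehg_oriented` signal set.
#' @param band analysis band (ignored when `x` is already oriented).
#' @param params an [xcorr_params()] object.
#' @param record_id identifier stored in the track (taken from the record when
#'   available).
#' @return object of class `ehg_track`: the parameter set plus a data frame
#'   `estimates` with columns `k`, `center_sample` (0-based), `s_v`, `s_h`,
#'   `t_v`, `t_h`, `cv`, `phi`, `direction`, `sector`.
#' @export
ehg_track <- function(x, band = "Bb", params = xcorr_params(),
                      record_id = NULL) {
  assert_that(inherits(params, "xcorr_params"), "params must be xcorr_params")
  if (inherits(x, "ehg_record")) {
    record_id <- record_id %||% x$record_id
    x <- preprocess_record(x, band)
  }
  assert_that(inherits(x, "ehg_oriented"),
              "x must be an ehg_record or ehg_oriented signal set")
  fs <- x$fs
  n <- length(x$S1)
  w <- round(params$w_c * fs)
  half <- w %/% 2L
  max_lag <- round(params$d_ss * fs)
  step <- params$d_ci * fs
  assert_that(n >= w, "record shorter than the correlation window",
              class = "ehg_empty_track_error")
  # 0-based centers: first at w_c/2, last with the window inside the record
  centers <- seq(half, n - (w - half), by = step)
  centers <- round(centers)
  nk <- length(centers)
  s_v <- s_h <- integer(nk)
  t_v <- t_h <- cv <- phi <- numeric(nk)
  direction <- sector <- character(nk)
  for (i in seq_len(nk)) {
    c0 <- centers[i]
    idx <- (c0 - half + 1L):(c0 - half + w)
    sv <- similarity_shift(window_normalize(x$S1[idx]),
                           window_normalize(x$S3[idx]), max_lag)
    sh <- similarity_shift(window_normalize(x$S2[idx]),
                           window_normalize(x$S4[idx]), max_lag)
    v <- shifts_to_velocity(sv, sh, fs, params$d_cm, params$cv_max)
    ds <- assign_sector(v$phi)
    s_v[i] <- sv; s_h[i] <- sh
    t_v[i] <- v$t_v; t_h[i] <- v$t_h; cv[i] <- v$cv; phi[i] <- v$phi
    direction[i] <- ds$direction; sector[i] <- ds$sector
  }
  structure(list(record_id = record_id %||% "unnamed", band = x$band,
                 params = params, fs = fs,
                 estimates = data.frame(
                   k = seq_len(nk), center_sample = centers, s_v = s_v,
                   s_h = s_h, t_v = t_v, t_h = t_h, cv = cv, phi = phi,
                   direction = direction, sector = sector,
                   stringsAsFactors = FALSE)),
            class = "ehg_track")
}

#' @export
print.ehg_track <- function(x, ...) {
  e <- x$estimates
  cat(sprintf("<ehg_track> %s, band %s: %d correlation intervals\n",
              x$record_id, x$band$name, nrow(e)))
  def <- e$cv > 0
  cat(sprintf("  propagation in %d intervals (%.1f%%); mean CV %.2f cm/s\n",
              sum(def), 100 * mean(def),
              if (any(def)) mean(e$cv[def]) else NA_real_))
  invisible(x)
}

#' @export
summary.ehg_track <- function(object, ...) {
  e <- object$estimates
  def <- e$cv > 0
  out <- list(
    record_id = object$record_id, band = object$band$name,
    n = nrow(e), n_defined = sum(def),
    mean_cv = if (any(def)) mean(e$cv[def]) else NA_real_,
    by_sector = table(factor(e$sector, c("south", "east", "north", "west"))),
    by_direction = table(factor(e$direction, c("vertical", "horizontal"))))
  class(out) <- "summary.ehg_track"
  out
}

#' @export
print.summary.ehg_track <- function(x, ...) {
  cat(sprintf("Velocity track of %s (band %s)\n", x$record_id, x$band))
  cat(sprintf("  %d correlation intervals, %d with propagation (%.1f%%)\n",
              x$n, x$n_defined, 100 * x$n_defined / x$n))
  cat(sprintf("  mean CV over defined intervals: %.2f cm/s\n", x$mean_cv))
  cat("  sectors: ")
  print(x$by_sector)
  invisible(x)
}

#' @export
as.data.frame.ehg_track <- function(x, ...) x$estimates

#' @export
plot.ehg_track <- function(x, ...) {
  e <- x$estimates
  t_s <- e$center_sample / x$fs
  graphics::plot(t_s, e$cv, type = "h", col = "grey40",
                 xlab = "time [s]", ylab = "CV [cm/s]",
                 main = sprintf("%s, band %s", x$record_id, x$band$name), ...)
  def <- e$cv > 0
  graphics::points(t_s[def], e$cv[def], pch = 20, cex = 0.4,
                   col = c(south = "firebrick", east = "steelblue",
                           north = "darkgreen", west = "orange")[e$sector[def]])
  invisible(x)
}

#' Serialize a velocity track to CSV
#'
#' Columns: `k`, `center_s`, `s_V`, `s_H`, `t_V`, `t_H`, `CV_cm_s`, `phi_deg`
#' (empty when undefined), `direction`, `sector`.
#'
#' @param track an `ehg_track`.
#' @param path output file.
#' @return Invisibly, `path`.
#' @export
write_track_csv <- function(track, path) {
  e <- track$estimates
  out <- data.frame(k = e$k, center_s = e$center_sample / track$fs,
                    s_V = e$s_v, s_H = e$s_h, t_V = e$t_v, t_H = e$t_h,
                    CV_cm_s = e$cv, phi_deg = e$phi,
                    direction = e$direction, sector = e$sector)
  utils::write.csv(out, path, row.names = FALSE, na = "")
  invisible(path)
}
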