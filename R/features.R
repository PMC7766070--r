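#' Propagation features of one annotated interval
#'
#' Aggregates the velocity estimates whose correlation-interval center falls
#' inside a half-open annotated interval `[start, end)` into the per-interval
#' propagation features: direction counts `N_V`, `N_H` and percentages
#' `P_V = 100 N_V / N`, `P_H = 100 N_H / N` (the denominator `N` counts every
#' correlation interval, including those without propagation), their ratio
#' `RP_VH`, the average conduction velocities by direction `Vbar_V`, `Vbar_H`
#' (means over `CV != 0` members only) and their ratio `RV_VH`, and the same
#' percentages/averages by sector (south, north, east, west). Ratios and means
#' whose denominator set is empty are flagged undefined (`NA`).
#'
#' @param track an [ehg_track()].
#' @param interval one-row interval as in [annotated_intervals()] (or a list
#'   with `start`, `end`, optionally `kind`).
#' @return one-row data frame of features.
#' @export
interval_features <- function(track, interval) {
  assert_that(inherits(track, "ehg_track"), "track must be an ehg_track")
  e <- track$estimates
  inside <- e$center_sample >= interval$start & e$center_sample < interval$end
  assert_that(any(inside), "interval contains no correlation-interval centers",
              class = "ehg_empty_feature_error")
  e <- e[inside, ]
  n <- nrow(e)
  mean_or_na <- function(v) if (length(v)) mean(v) else NA_real_
  ratio_or_na <- function(a, b) if (!is.na(a) && !is.na(b) && b != 0) a / b else NA_real_
  cnt <- function(sel) sum(sel, na.rm = TRUE)
  n_v <- cnt(e$direction == "vertical")
  n_h <- cnt(e$direction == "horizontal")
  p_v <- 100 * n_v / n
  p_h <- 100 * n_h / n
  vbar <- function(sel) mean_or_na(e$cv[which(sel)])
  vbar_v <- vbar(e$direction == "vertical")
  vbar_h <- vbar(e$direction == "horizontal")
  sec_p <- vapply(c("south", "north", "east", "west"),
                  function(s) 100 * cnt(e$sector == s) / n, numeric(1))
  sec_v <- vapply(c("south", "north", "east", "west"),
                  function(s) vbar(e$sector == s), numeric(1))
  data.frame(
    interval_kind = interval$kind %||% NA_character_,
    start = interval$start, end = interval$end,
    N = n, N_V = n_v, N_H = n_h,
    P_V = p_v, P_H = p_h, RP_VH = ratio_or_na(p_v, p_h),
    Vbar_V = vbar_v, Vbar_H = vbar_h, RV_VH = ratio_or_na(vbar_v, vbar_h),
    P_S = sec_p[["south"]], P_N = sec_p[["north"]],
    P_E = sec_p[["east"]], P_W = sec_p[["west"]],
    Vbar_S = sec_v[["south"]], Vbar_N = sec_v[["north"]],
    Vbar_E = sec_v[["east"]], Vbar_W = sec_v[["west"]],
    stringsAsFactors = FALSE)
}

#' Sample entropy
#'
#' `SampEn(m, r) = -ln(A / B)` where `B` counts ordered template pairs of
#' length `m` and `A` of length `m + 1` within Chebyshev distance `r` of each
#' other, self-matches excluded and both counts taken over templates starting
#' at `1..N-m`. The matching margin is `r` times the standard deviation of the
#' segment (the convention of the sample-entropy literature; set
#' `r_mode = "absolute"` to pass an absolute margin). Degenerate cases
#' (constant input, no template matches at either length) are flagged
#' undefined (`NA`).
#'
#' @param x numeric series with `length(x) > m + 1`.
#' @param m template length (default 3).
#' @param r matching margin (default 0.15), a fraction of `sd(x)` unless
#'   `r_mode = "absolute"`.
#' @param r_mode `"sd"` or `"absolute"`.
#' @return sample entropy (dimensionless), or `NA` when undefined.
#' @export
sample_entropy <- function(x, m = 3, r = 0.15, r_mode = c("sd", "absolute")) {
  r_mode <- match.arg(r_mode)
  assert_that(is_count(m) && m >= 1, "m must be a positive integer",
              class = "ehg_parameter_error")
  assert_that(r > 0, "r must be > 0", class = "ehg_parameter_error")
  n <- length(x)
  assert_that(n > m + 1, "series too short for template length m",
              class = "ehg_parameter_error")
  tol <- if (r_mode == "sd") r * stats::sd(x) else r
  if (!is.finite(tol) || tol == 0) return(NA_real_)
  nt <- n - m            # templates of length m and m+1 both start at 1..n-m
  a <- 0; b <- 0
  for (i in seq_len(nt - 1L)) {
    j <- (i + 1L):nt
    dmax <- abs(x[j] - x[i])
    for (k in seq_len(m - 1L))
      dmax <- pmax(dmax, abs(x[j + k] - x[i + k]))
    match_m <- dmax <= tol
    b <- b + sum(match_m)
    if (any(match_m))
      a <- a + sum(abs(x[j[match_m] + m] - x[i + m]) <= tol)
  }
  if (a == 0 || b == 0) return(NA_real_)
  -log(a / b)
}

#' Feature table over records, intervals and bands
#'
#' Runs the full feature extraction: for each record and band the record is
#' preprocessed, velocity-tracked, and each annotated interval reduced to its
#' propagation features; sample entropies `SE_S2` and `SE_S3` are computed on
#' the band-filtered S2/S3 segments cropped to the interval. One row per
#' (record, interval, band); intervals that cannot be reduced (for example no
#' correlation center inside) yield a flagged row of `NA` features rather
#' than being dropped.
#'
#' @param records list of [ehg_record()] objects (with annotations).
#' @param bands character vector of band names (default all five analysis
#'   bands).
#' @param params an [xcorr_params()].
#' @param sampen list with elements `m` and `r` for [sample_entropy()].
#' @return data frame with columns `record_id`, `group`, `interval_kind`,
#'   `band`, `N`, `P_V`, `P_H`, `RP_VH`, `Vbar_V`, `Vbar_H`, `RV_VH`, `P_S`,
#'   `P_N`, `P_E`, `P_W`, `Vbar_S`, `Vbar_N`, `Vbar_E`, `Vbar_W`, `SE_S2`,
#'   `SE_S3` (NA = undefined).
#' @export
ehg_features <- function(records, bands = c("B0p", "Bb", "B1", "B2", "B3"),
                         params = xcorr_params(),
                         sampen = list(m = 3, r = 0.15)) {
  if (inherits(records, "ehg_record")) records <- list(records)
  rows <- list()
  for (rec in records) {
    assert_that(inherits(rec, "ehg_record"), "records must be ehg_record objects")
    assert_that(nrow(rec$annotations) > 0L, "record ", rec$record_id,
                " carries no annotations", class = "ehg_structural_error")
    for (bname in bands) {
      oriented <- preprocess_record(rec, bname)
      track <- ehg_track(oriented, params = params, record_id = rec$record_id)
      for (ii in seq_len(nrow(rec$annotations))) {
        iv <- rec$annotations[ii, ]
        seg <- (iv$start + 1L):iv$end
        fe <- tryCatch(interval_features(track, iv), error = function(e) NULL)
        se2 <- tryCatch(sample_entropy(oriented$S2[seg], sampen$m, sampen$r),
                        error = function(e) NA_real_)
        se3 <- tryCatch(sample_entropy(oriented$S3[seg], sampen$m, sampen$r),
                        error = function(e) NA_real_)
        base <- data.frame(record_id = rec$record_id, group = rec$group,
                           interval_kind = iv$kind, band = bname,
                           stringsAsFactors = FALSE)
        if (is.null(fe)) {
          fe <- data.frame(N = NA_integer_, P_V = NA_real_, P_H = NA_real_,
                           RP_VH = NA_real_, Vbar_V = NA_real_,
                           Vbar_H = NA_real_, RV_VH = NA_real_,
                           P_S = NA_real_, P_N = NA_real_, P_E = NA_real_,
                           P_W = NA_real_, Vbar_S = NA_real_,
                           Vbar_N = NA_real_, Vbar_E = NA_real_,
                           Vbar_W = NA_real_)
        } else {
          fe <- fe[, c("N", "P_V", "P_H", "RP_VH", "Vbar_V", "Vbar_H",
                       "RV_VH", "P_S", "P_N", "P_E", "P_W", "Vbar_S",
                       "Vbar_N", "Vbar_E", "Vbar_W")]
        }
        rows[[length(rows) + 1L]] <- cbind(base, fe,
                                           data.frame(SE_S2 = se2, SE_S3 = se3))
      }
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Write a feature table to CSV
#'
#' @param features data frame from [ehg_features()].
#' @param path output file; undefined cells are written empty.
#' @return Invisibly, `path`.
#' @export
write_features_csv <- function(features, path) {
  utils::write.csv(features, path, row.names = FALSE, na = "")
  invisible(path)
}
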