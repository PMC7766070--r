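# Independent oracles and small constructors shared across tests.

# Literal double-loop evaluation of the windowed cross-correlation
# C(m) = sum_n x(n) y(n-m), scaled by the number of overlapping terms,
# argmax with ties broken toward smallest |m| then negative m.
brute_shift <- function(x, y, max_lag) {
  n <- length(x)
  best_m <- NA_integer_
  best_c <- -Inf
  for (m in order(abs(-max_lag:max_lag), -max_lag:max_lag) - max_lag - 1L) {
    s <- 0
    cnt <- 0L
    for (nn in seq_len(n)) {
      j <- nn - m
      if (j >= 1L && j <= n) {
        s <- s + x[nn] * y[j]
        cnt <- cnt + 1L
      }
    }
    cm <- s / cnt
    if (cm > best_c) {
      best_c <- cm
      best_m <- as.integer(m)
    }
  }
  best_m
}

# Brute-force sample entropy by full pairwise distance matrices
# (independent of the package's row-accumulating implementation).
brute_sampen <- function(x, m = 3, r = 0.15) {
  tol <- r * stats::sd(x)
  n <- length(x)
  nt <- n - m
  E <- sapply(0:m, function(k) x[(1:nt) + k])  # nt x (m+1) embedding
  dmat <- matrix(0, nt, nt)
  for (k in 1:m)
    dmat <- pmax(dmat, abs(outer(E[, k], E[, k], "-")))
  match_m <- dmat <= tol
  diag(match_m) <- FALSE
  b <- sum(match_m) / 2
  dmat1 <- pmax(dmat, abs(outer(E[, m + 1], E[, m + 1], "-")))
  match_m1 <- dmat1 <= tol
  diag(match_m1) <- FALSE
  a <- sum(match_m1) / 2
  if (a == 0 || b == 0) return(NA_real_)
  -log(a / b)
}

# Hand-built velocity track for feature arithmetic tests.
make_track <- function(cv, sector, fs = 20, d_ci = 0.5) {
  stopifnot(length(cv) == length(sector))
  dir_of <- c(south = "vertical", north = "vertical",
              east = "horizontal", west = "horizontal")
  phi_of <- c(south = 0, north = -180, east = 90, west = -90)
  n <- length(cv)
  est <- data.frame(
    k = seq_len(n),
    center_sample = 50 + (seq_len(n) - 1) * d_ci * fs,
    s_v = 0L, s_h = 0L, t_v = 0, t_h = 0, cv = cv,
    phi = ifelse(cv > 0, phi_of[sector], NA_real_),
    direction = ifelse(cv > 0, dir_of[sector], NA_character_),
    sector = ifelse(cv > 0, sector, NA_character_),
    stringsAsFactors = FALSE)
  structure(list(record_id = "handmade", band = band_spec("B1"),
                 params = xcorr_params(), fs = fs, estimates = est),
            class = "ehg_track")
}

# Lag of the maximum of the raw (centered-signal) cross-correlation,
# used for zero-phase checks.
raw_xcorr_peak <- function(x, y, max_lag = 10) {
  n <- length(x)
  lags <- -max_lag:max_lag
  cc <- vapply(lags, function(m) {
    if (m >= 0) sum(x[(1 + m):n] * y[1:(n - m)])
    else sum(x[1:(n + m)] * y[(1 - m):n])
  }, numeric(1))
  lags[which.max(cc)]
}
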