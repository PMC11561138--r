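# Small numeric utilities shared across modules. All are internal.

# population (divide-by-n) standard deviation; used for all inter-subject
# spread statistics
sd_pop <- function(x) {
  x <- x[is.finite(x)]
  if (length(x) == 0L) return(NA_real_)
  sqrt(mean((x - mean(x))^2))
}

deg2rad <- function(x) x * pi / 180
rad2deg <- function(x) x * 180 / pi

clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

# quintic smoothstep on [0,1]: C2, zero first/second derivative at both ends
smootherstep <- function(u) {
  u <- clamp(u, 0, 1)
  u^3 * (10 - 15 * u + 6 * u^2)
}

# centred moving average with edge replication; n must be odd
moving_average <- function(x, n = 5L) {
  if (n <= 1L || length(x) < 2L) return(x)
  half <- (n - 1L) %/% 2L
  xp <- c(rep(x[1L], half), x, rep(x[length(x)], half))
  as.numeric(stats::filter(xp, rep(1 / n, n), sides = 2L))[(half + 1L):(half + length(x))]
}

# strict interior local maxima (greater than both neighbours)
local_maxima <- function(x) {
  n <- length(x)
  if (n < 3L) return(integer(0))
  which(x[2:(n - 1L)] > x[1:(n - 2L)] & x[2:(n - 1L)] > x[3:n]) + 1L
}

# topographic prominence of peak at index i: height above the higher of the
# two saddle minima separating it from larger terrain on each side
peak_prominence <- function(x, idx) {
  vapply(idx, function(i) {
    left <- x[seq_len(i)]
    higher_l <- which(left > x[i])
    lmin <- if (length(higher_l)) min(left[max(higher_l):i]) else min(left)
    right <- x[i:length(x)]
    higher_r <- which(right > x[i])
    rmin <- if (length(higher_r)) min(right[1:min(higher_r)]) else min(right)
    x[i] - max(lmin, rmin)
  }, numeric(1))
}

# peak picking with a minimum separation (keep taller peak on conflict) and a
# minimum prominence
find_peaks <- function(x, min_dist = 1L, min_prominence = 0) {
  cand <- local_maxima(x)
  if (!length(cand)) return(integer(0))
  prom <- peak_prominence(x, cand)
  cand <- cand[prom >= min_prominence]
  if (!length(cand)) return(integer(0))
  ord <- cand[order(x[cand], decreasing = TRUE)]
  kept <- integer(0)
  for (i in ord) {
    if (!length(kept) || all(abs(kept - i) >= min_dist)) kept <- c(kept, i)
  }
  sort(kept)
}

# zero-phase low-pass Butterworth (order 2) with reflective end-padding to
# suppress filtfilt edge transients; identity for very short series
lowpass <- function(x, cutoff_hz, fs, order = 2L) {
  n <- length(x)
  if (n < 3L * (order + 1L)) return(x)
  pad <- min(n - 1L, ceiling(3 * fs / cutoff_hz))
  xp <- c(2 * x[1L] - x[(pad + 1L):2L], x, 2 * x[n] - x[(n - 1L):(n - pad)])
  bf <- signal::butter(order, min(cutoff_hz / (fs / 2), 0.99), type = "low")
  y <- as.numeric(signal::filtfilt(bf, xp))
  y[(pad + 1L):(pad + n)]
}

# Savitzky-Golay smoothing that degrades gracefully on short inputs
sg_smooth <- function(x, p = 3L, n = 11L) {
  n <- min(n, if (length(x) %% 2L == 0L) length(x) - 1L else length(x))
  if (n %% 2L == 0L) n <- n - 1L
  if (n <= p + 1L) return(x)
  as.numeric(signal::sgolayfilt(x, p = p, n = n))
}

# least-absolute-deviations straight line fit by iteratively reweighted least
# squares; returns c(intercept, slope)
lad_line <- function(t, y, iter = 30L, eps = 1e-8) {
  X <- cbind(1, t)
  beta <- stats::lm.fit(X, y)$coefficients
  beta[is.na(beta)] <- 0
  for (k in seq_len(iter)) {
    r <- as.numeric(y - X %*% beta)
    w <- 1 / pmax(abs(r), eps)
    bw <- stats::lm.fit(X * sqrt(w), y * sqrt(w))$coefficients
    bw[is.na(bw)] <- 0
    if (max(abs(bw - beta)) < 1e-12) {
      beta <- bw
      break
    }
    beta <- bw
  }
  as.numeric(beta)
}

# cubic Hermite segment: values at integer offsets 0..(n-1) from endpoint
# values p0/p1 and endpoint slopes m0/m1 given per sample step
hermite_segment <- function(n, p0, p1, m0, m1) {
  if (n <= 0L) return(numeric(0))
  if (n == 1L) return(p0)
  s <- seq(0, 1, length.out = n)
  L <- n - 1L
  h00 <- 2 * s^3 - 3 * s^2 + 1
  h10 <- s^3 - 2 * s^2 + s
  h01 <- -2 * s^3 + 3 * s^2
  h11 <- s^3 - s^2
  h00 * p0 + h10 * (m0 * L) + h01 * p1 + h11 * (m1 * L)
}

# second central difference; endpoints replicate their neighbour
second_diff <- function(x, dt) {
  n <- length(x)
  if (n < 3L) return(rep(0, n))
  a <- c(0, (x[3:n] - 2 * x[2:(n - 1L)] + x[1:(n - 2L)]) / dt^2, 0)
  a[1L] <- a[2L]
  a[n] <- a[n - 1L]
  a
}
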