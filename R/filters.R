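# Digital Bessel band-pass design and zero-phase filtering.
# No signal-processing package ships with the runtime, so the filter chain is
# built here: reversed-Bessel-polynomial analog prototype, -3 dB magnitude
# normalization, lowpass->bandpass pole transform, bilinear transform with
# frequency prewarping, second-order sections, and a scipy-style filtfilt
# (odd-extension padding plus per-section steady-state initial conditions).

# coefficients of the reversed Bessel polynomial theta_n (ascending powers of s
# would be messy; return descending: c(1, ...) for s^n ... s^0) via the
# recurrence theta_n = (2n-1) theta_{n-1} + s^2 theta_{n-2}
bessel_poly <- function(order) {
  th_prev <- 1           # theta_0
  th <- c(1, 1)          # theta_1 (descending: s + 1)
  if (order == 0) return(th_prev)
  if (order == 1) return(th)
  for (k in 2:order) {
    a <- (2 * k - 1) * c(0, th)                 # degree k-1 -> pad to k
    b <- c(th_prev, 0, 0)                       # s^2 * theta_{k-2}, degree k
    len <- max(length(a), length(b))
    th_new <- c(rep(0, len - length(a)), a) + c(rep(0, len - length(b)), b)
    th_prev <- th
    th <- th_new
  }
  th
}

# analog Bessel lowpass prototype, -3 dB magnitude at omega = 1:
# list(poles = complex, gain = real)
bessel_prototype <- function(order) {
  coef <- bessel_poly(order)
  poles <- polyroot(rev(coef))
  k <- coef[length(coef)] # theta_n(0): |H(0)| = 1
  mag2 <- function(w) {
    h <- abs(k / vapply(w, function(wi)
      sum(rev(coef) * (1i * wi)^(0:order)), complex(1)))^2
    h
  }
  w3 <- stats::uniroot(function(w) mag2(w) - 0.5, c(1e-6, 10 * order),
                       tol = 1e-12)$root
  poles <- poles / w3
  list(poles = poles, gain = Re(prod(-poles)))
}

# zpk of a digital Bessel band-pass as second-order sections
# low, high in Hz; rate in Hz
bessel_bandpass_sos <- function(low, high, rate, order = 3) {
  if (low <= 0 || high <= low || high >= rate / 2)
    stop("need 0 < low < high < rate/2")
  proto <- bessel_prototype(order)
  fs2 <- 2 * rate
  # prewarped analog band edges (rad/s): Omega = 2 fs tan(pi f / fs)
  wl <- 2 * rate * tan(pi * low / rate)
  wh <- 2 * rate * tan(pi * high / rate)
  w0 <- sqrt(wl * wh)
  bw <- wh - wl
  # lowpass pole p -> pair of bandpass poles
  p_bp <- unlist(lapply(proto$poles, function(p) {
    t1 <- p * bw / 2
    disc <- sqrt(t1^2 - w0^2 + 0i)
    c(t1 + disc, t1 - disc)
  }))
  k_bp <- proto$gain * bw^order
  # bilinear transform; analog zeros: `order` zeros at s = 0
  pd <- (fs2 + p_bp) / (fs2 - p_bp)
  zd <- c(rep(1 + 0i, order), rep(-1 + 0i, order)) # s=0 -> z=1; extras at -1
  kd <- Re(k_bp * fs2^order / prod(fs2 - p_bp))
  # pair poles into conjugate sections, each with zeros (z-1)(z+1)
  ps <- pd[order(abs(Im(pd)), Re(pd))]
  used <- rep(FALSE, length(ps))
  sections <- list()
  for (i in seq_along(ps)) {
    if (used[i]) next
    used[i] <- TRUE
    if (abs(Im(ps[i])) > 1e-10) {
      j <- which(!used & abs(ps - Conj(ps[i])) < 1e-8)[1]
      if (is.na(j)) stop("unpaired complex pole in filter design")
      used[j] <- TRUE
      pair <- c(ps[i], ps[j])
    } else {
      j <- which(!used & abs(Im(ps)) <= 1e-10)[1]
      used[j] <- TRUE
      pair <- c(ps[i], ps[j])
    }
    a <- Re(c(1, -(pair[1] + pair[2]), pair[1] * pair[2]))
    sections[[length(sections) + 1]] <- c(1, 0, -1, a)
  }
  sos <- do.call(rbind, sections)
  sos <- sos[, c(1, 2, 3, 4, 5, 6), drop = FALSE]
  sos[1, 1:3] <- sos[1, 1:3] * kd
  colnames(sos) <- c("b0", "b1", "b2", "a0", "a1", "a2")
  sos
}

# per-section steady-state (step-response) initial conditions, scipy-style;
# returns n_sections x 2, to be scaled by the first input sample
sos_zi <- function(sos) {
  ns <- nrow(sos)
  zi <- matrix(0, ns, 2)
  scale <- 1
  for (s in seq_len(ns)) {
    b0 <- sos[s, 1]; b1 <- sos[s, 2]; b2 <- sos[s, 3]
    a1 <- sos[s, 5]; a2 <- sos[s, 6]
    h1 <- (b0 + b1 + b2) / (1 + a1 + a2)
    zi[s, 1] <- scale * (h1 - b0)
    zi[s, 2] <- scale * (b2 - a2 * h1)
    scale <- scale * h1
  }
  zi
}

# zero-phase forward-backward SOS filtering with odd-extension padding
filtfilt_sos <- function(sos, x, padlen = NULL) {
  T <- length(x)
  if (is.null(padlen)) padlen <- 3 * (2 * nrow(sos) + 1)
  padlen <- min(padlen, T - 1)
  if (padlen < 1) stop("signal too short for the filter warm-up")
  front <- 2 * x[1] - x[(padlen + 1):2]
  back <- 2 * x[T] - x[(T - 1):(T - padlen)]
  ext <- c(front, x, back)
  zi <- sos_zi(sos)
  y <- sosfilt_cpp(sos, ext, zi * ext[1])
  y <- rev(y)
  y <- sosfilt_cpp(sos, y, zi * y[1])
  y <- rev(y)
  y[(padlen + 1):(padlen + T)]
}

# pad length covering ~3 periods of the lowest passband frequency
bandpass_padlen <- function(rate, low, T) min(T - 1, ceiling(3 * rate / low))

#' Band-pass filter a multichannel signal with a zero-phase Bessel filter
#'
#' @param x n x T matrix (channels x samples).
#' @param rate sampling rate (Hz).
#' @param low,high band edges (Hz).
#' @param order analog prototype order (default 3).
#' @return Filtered n x T matrix.
#' @export
bessel_bandpass <- function(x, rate, low, high, order = 3) {
  if (is.vector(x)) x <- matrix(x, 1)
  sos <- bessel_bandpass_sos(low, high, rate, order)
  padlen <- bandpass_padlen(rate, low, ncol(x))
  out <- x
  for (i in seq_len(nrow(x))) out[i, ] <- filtfilt_sos(sos, x[i, ], padlen)
  out
}

# analytic-signal phase via FFT Hilbert transform
hilbert_phase <- function(x) {
  T <- length(x)
  X <- fft(x)
  h <- numeric(T)
  if (T %% 2 == 0) {
    h[1] <- 1; h[T / 2 + 1] <- 1; h[2:(T / 2)] <- 2
  } else {
    h[1] <- 1; h[2:((T + 1) / 2)] <- 2
  }
  Arg(fft(X * h, inverse = TRUE) / T)
}

# block-mean decimation by an integer factor (anti-aliasing boxcar)
decimate_mean <- function(x, factor) {
  if (factor <= 1) return(x)
  if (is.vector(x)) x <- matrix(x, 1)
  T2 <- floor(ncol(x) / factor)
  acc <- x[, seq(1, by = factor, length.out = T2), drop = FALSE]
  for (o in 2:factor)
    acc <- acc + x[, seq(o, by = factor, length.out = T2), drop = FALSE]
  acc / factor
}

# Welch spectral peak within [fmin, fmax]; Hann window, 50% overlap.
# Returns NA for flat signals.
welch_peak <- function(x, rate, fmin = 2, fmax = 20, seg_sec = 4) {
  T <- length(x)
  if (sd(x) == 0) return(NA_real_)
  L <- min(T, round(seg_sec * rate))
  step <- max(1, floor(L / 2))
  starts <- seq(1, T - L + 1, by = step)
  win <- 0.5 * (1 - cos(2 * pi * seq_len(L) / (L + 1)))
  psd <- 0
  for (s0 in starts) {
    seg <- x[s0:(s0 + L - 1)]
    seg <- (seg - mean(seg)) * win
    psd <- psd + Mod(fft(seg)[1:(floor(L / 2) + 1)])^2
  }
  freqs <- (0:floor(L / 2)) * rate / L
  keep <- freqs >= fmin & freqs <= fmax
  if (!any(keep) || all(psd[keep] == 0)) return(NA_real_)
  freqs[keep][which.max(psd[keep])]
}
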