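#' Kuramoto phase synchrony of EEG-like signals
#'
#' Each channel is band-pass filtered (zero-phase 3rd-order Bessel) around
#' its own spectral peak (Welch periodogram, search restricted to
#' `peak_range`) +/- `half_band` Hz, the instantaneous phase is extracted
#' with the Hilbert transform (first/last second discarded against edge
#' artifacts), and the order parameter R(t) = |mean_i exp(j theta_i(t))| is
#' averaged over time.
#'
#' Signals are block-averaged down to at most `max_rate` before analysis;
#' the band of interest is well below that Nyquist.
#'
#' @param nu n x T matrix of EEG-like signals (or a `neural_trace`).
#' @param rate sampling rate (Hz; taken from the trace if given one).
#' @param half_band half-width of the per-node band (Hz, default 3).
#' @param peak_range spectral peak search range (Hz, default c(2, 20)).
#' @param max_rate analysis rate ceiling (Hz, default 250).
#' @param trim_sec seconds of phase discarded at each end (default 1).
#' @return List with `R_bar` (time-averaged order parameter), `R_t`,
#'   `theta` (n x T' phase matrix), `band` (n x 2 per-node band), `rate`.
#' @export
phase_synchrony <- function(nu, rate = NULL, half_band = 3,
                            peak_range = c(2, 20), max_rate = 250,
                            trim_sec = 1) {
  if (inherits(nu, "neural_trace")) {
    rate <- nu$rate
    nu <- nu$nu
  }
  if (inherits(nu, "fixture_signals")) {
    rate <- nu$rate
    nu <- nu$traces
  }
  if (is.null(rate)) stop("sampling rate required")
  n <- nrow(nu)
  if (ncol(nu) / rate < 2) stop("need at least 2 s of signal")
  fac <- max(1L, floor(rate / max_rate))
  if (fac > 1) {
    nu <- decimate_mean(nu, fac)
    rate <- rate / fac
  }
  T <- ncol(nu)
  theta <- matrix(0, n, T)
  band <- matrix(0, n, 2)
  sos_cache <- new.env()
  for (i in seq_len(n)) {
    pk <- welch_peak(nu[i, ], rate, peak_range[1], peak_range[2])
    if (is.na(pk))
      stop(sprintf("no spectral peak found for node %d (flat signal?)", i))
    lo <- max(pk - half_band, 0.1)
    hi <- min(pk + half_band, rate / 2 * 0.95)
    band[i, ] <- c(lo, hi)
    key <- sprintf("%.6f_%.6f", lo, hi)
    if (is.null(sos_cache[[key]]))
      sos_cache[[key]] <- bessel_bandpass_sos(lo, hi, rate, 3)
    xf <- filtfilt_sos(sos_cache[[key]], nu[i, ], bandpass_padlen(rate, lo, T))
    theta[i, ] <- hilbert_phase(xf)
  }
  trim <- min(round(trim_sec * rate), floor((T - 2) / 2))
  keep <- (trim + 1):(T - trim)
  Rt <- Mod(colMeans(exp(1i * theta[, keep, drop = FALSE])))
  list(R_bar = mean(Rt), R_t = Rt, theta = theta[, keep, drop = FALSE],
       band = band, rate = rate)
}

# Fourier-transform surrogate: randomized phases, amplitude spectrum kept.
# x is a vector; conjugate symmetry (and real DC/Nyquist) is enforced.
ft_surrogate <- function(x) {
  T <- length(x)
  X <- fft(x)
  half <- floor(T / 2)
  ph <- runif(half - if (T %% 2 == 0) 1 else 0, 0, 2 * pi)
  rot <- complex(modulus = 1, argument = ph)
  Xs <- X
  if (T %% 2 == 0) {
    Xs[2:half] <- X[2:half] * rot
    Xs[(half + 2):T] <- Conj(rev(Xs[2:half]))
  } else {
    Xs[2:(half + 1)] <- X[2:(half + 1)] * rot
    Xs[(half + 2):T] <- Conj(rev(Xs[2:(half + 1)]))
  }
  Re(fft(Xs, inverse = TRUE)) / T
}

#' Surrogate-thresholded functional connectivity
#'
#' Pearson correlations of the full time series, thresholded against a null
#' of Fourier-transform surrogates: per channel the Fourier phases are
#' randomized (amplitude spectrum preserved), a Gaussian is fitted to each
#' pair's surrogate correlations, one-sided (right-tail) p-values are
#' corrected with Benjamini-Hochberg FDR, and non-significant or negative
#' entries are zeroed.
#'
#' @param bold a `bold_trace`, `fixture_signals`, or n x T matrix.
#' @param n_surrogates surrogate datasets (default 500).
#' @param q FDR level (default 0.05).
#' @param seed integer RNG seed.
#' @return An object of class `fc_matrix`: list with `values` (raw Pearson),
#'   `thresholded` (non-negative, significant entries only), `mask`, `p`.
#' @export
fc_threshold <- function(bold, n_surrogates = 500, q = 0.05, seed = NULL) {
  x <- if (inherits(bold, "bold_trace")) bold$bold
       else if (inherits(bold, "fixture_signals")) bold$traces
       else as.matrix(bold)
  n <- nrow(x)
  if (n < 2) stop("need at least 2 channels")
  if (any(apply(x, 1, sd) == 0)) stop("constant channel: correlation undefined")
  fc <- cor(t(x))
  ut <- upper.tri(fc)
  m1 <- matrix(0, n, n)
  m2 <- matrix(0, n, n)
  with_seed(seed, for (s in seq_len(n_surrogates)) {
    xs <- t(apply(x, 1, ft_surrogate))
    cs <- cor(t(xs))
    m1 <- m1 + cs
    m2 <- m2 + cs^2
  })
  mu <- m1 / n_surrogates
  sdv <- sqrt(pmax(m2 / n_surrogates - mu^2, 0)) * sqrt(n_surrogates / (n_surrogates - 1))
  p <- matrix(1, n, n)
  p[ut] <- 1 - pnorm(fc[ut], mu[ut], pmax(sdv[ut], 1e-12))
  p_adj <- p
  p_adj[ut] <- p.adjust(p[ut], method = "BH")
  mask <- matrix(FALSE, n, n)
  mask[ut] <- p_adj[ut] <= q
  mask <- mask | t(mask)
  thr <- ifelse(mask & fc > 0, fc, 0)
  diag(thr) <- 0
  dimnames(thr) <- dimnames(fc)
  structure(list(values = fc, thresholded = thr, mask = mask, p = p_adj),
            class = "fc_matrix")
}

#' Weighted global efficiency of a thresholded FC matrix
#'
#' Mean inverse shortest path length over ordered node pairs, with path
#' lengths accumulated over inverse weights; disconnected pairs contribute 0.
#'
#' @param fc an `fc_matrix` (its `thresholded` slot is used) or a
#'   non-negative matrix.
#' @return Scalar global efficiency.
#' @export
global_efficiency <- function(fc) {
  W <- if (inherits(fc, "fc_matrix")) fc$thresholded else as.matrix(fc)
  n <- nrow(W)
  inv <- inverse_distance_matrix(W)
  sum(inv) / (n * (n - 1))
}

#' Consensus Louvain modularity
#'
#' Runs seeded Louvain `runs` times on the (thresholded, non-negative) FC
#' graph, builds the co-assignment agreement matrix, zeroes entries below
#' `agreement_threshold`, and iterates Louvain on the agreement graph until
#' all runs return the same partition (capped at `max_rounds`). The reported
#' modularity is that of the consensus partition on the original graph.
#'
#' @param fc an `fc_matrix` or non-negative matrix.
#' @param gamma Louvain resolution (default 1.0).
#' @param runs Louvain repetitions per round (default 200).
#' @param agreement_threshold absolute threshold on the agreement matrix
#'   (default 0.5).
#' @param seed integer RNG seed.
#' @param max_rounds consensus iteration cap (default 20).
#' @return List with `Q_w`, `membership` (integer vector), `n_modules`.
#' @export
modularity_consensus <- function(fc, gamma = 1.0, runs = 200,
                                 agreement_threshold = 0.5, seed = NULL,
                                 max_rounds = 20) {
  W <- if (inherits(fc, "fc_matrix")) fc$thresholded else as.matrix(fc)
  n <- nrow(W)
  if (all(W == 0)) stop("empty graph: no modules to detect")
  louvain_many <- function(A, k) {
    g <- igraph::graph_from_adjacency_matrix(A, mode = "undirected",
                                             weighted = TRUE, diag = FALSE)
    lapply(seq_len(k), function(i)
      igraph::membership(igraph::cluster_louvain(g, resolution = gamma)))
  }
  with_seed(seed, {
    parts <- louvain_many(W, runs)
    for (round in seq_len(max_rounds)) {
      canon <- vapply(parts, function(p) paste(match(p, unique(p)), collapse = ","),
                      character(1))
      if (length(unique(canon)) == 1) break
      G <- matrix(0, n, n)
      for (p in parts) G <- G + outer(p, p, "==")
      G <- G / length(parts)
      diag(G) <- 0
      G[G < agreement_threshold] <- 0
      if (all(G == 0)) break # no agreement: keep current partitions
      parts <- louvain_many(G, runs)
    }
    membership <- as.integer(match(parts[[1]], unique(parts[[1]])))
    g0 <- igraph::graph_from_adjacency_matrix(W, mode = "undirected",
                                              weighted = TRUE, diag = FALSE)
    Q <- igraph::modularity(g0, membership, weights = igraph::E(g0)$weight)
    list(Q_w = Q, membership = membership, n_modules = length(unique(membership)))
  })
}

#' Functional connectivity dynamics (FCD) matrix
#'
#' Sliding-window FC (Pearson) with windows of `window` seconds displaced by
#' `step` seconds; each window's upper-triangle FC vector is normalized to
#' unit length and pairs of windows are compared with the Clarkson distance
#' lambda(x, y) = 1/2 || x/||x|| - y/||y|| ||, giving a W x W matrix with
#' entries in [0, 1].
#'
#' @param bold a `bold_trace` or n x T matrix.
#' @param rate sampling rate (Hz) when a bare matrix is given.
#' @param window window length (s, default 100).
#' @param step window displacement (s, default 2).
#' @return An object of class `fcd_matrix`: list with `values` (W x W),
#'   `window`, `step`, `n_windows`.
#' @export
fcd <- function(bold, rate = NULL, window = 100, step = 2) {
  x <- if (inherits(bold, "bold_trace")) { rate <- bold$rate; bold$bold }
       else as.matrix(bold)
  if (is.null(rate)) stop("sampling rate required")
  T <- ncol(x)
  wlen <- round(window * rate)
  wstep <- max(1L, round(step * rate))
  if (T < wlen) stop("signal shorter than one window")
  W <- floor((T - wlen) / wstep) + 1
  ut <- upper.tri(diag(nrow(x)))
  vecs <- vapply(seq_len(W), function(k) {
    i0 <- (k - 1) * wstep + 1
    v <- cor(t(x[, i0:(i0 + wlen - 1), drop = FALSE]))[ut]
    v / sqrt(sum(v^2))
  }, numeric(sum(ut)))
  D <- matrix(0, W, W)
  for (i in seq_len(W - 1)) {
    d <- sqrt(colSums((vecs[, (i + 1):W, drop = FALSE] - vecs[, i])^2)) / 2
    D[i, (i + 1):W] <- d
    D[(i + 1):W, i] <- d
  }
  # (pairwise entries equal clarkson_distance of the unnormalized vectors)
  structure(list(values = D, window = window, step = step, n_windows = W),
            class = "fcd_matrix")
}

# Clarkson distance between two FC vectors: half the Euclidean distance of
# the unit-normalized vectors; in [0, 1] for any inputs
clarkson_distance <- function(x, y) {
  sqrt(sum((x / sqrt(sum(x^2)) - y / sqrt(sum(y^2)))^2)) / 2
}

#' Summarize the functional state of one simulated run
#'
#' Convenience composition: Kuramoto phase synchrony from the EEG-like
#' traces, and global efficiency plus consensus modularity from the
#' surrogate-thresholded FC of the band-passed BOLD.
#'
#' @param trace a `neural_trace`.
#' @param seed RNG seed for the FC surrogates and Louvain.
#' @param measures subset of c("R_bar", "E_w", "Q_w") to compute.
#' @param fc_surrogates surrogates for [fc_threshold].
#' @param louvain_runs runs for [modularity_consensus].
#' @param ... passed to [bandpass_bold].
#' @return List with `R_bar`, `E_w`, `Q_w`, `membership` (NA when skipped).
#' @export
functional_summary <- function(trace, seed = 1,
                               measures = c("R_bar", "E_w", "Q_w"),
                               fc_surrogates = 500, louvain_runs = 200, ...) {
  out <- list(R_bar = NA_real_, E_w = NA_real_, Q_w = NA_real_,
              membership = NULL)
  if ("R_bar" %in% measures)
    out$R_bar <- phase_synchrony(trace)$R_bar
  if (any(c("E_w", "Q_w") %in% measures)) {
    raw <- bold_forward(trace)
    bt <- bandpass_bold(raw, rate = trace$rate, ...)
    fc <- fc_threshold(bt, n_surrogates = fc_surrogates, seed = seed)
    if ("E_w" %in% measures) out$E_w <- global_efficiency(fc)
    if ("Q_w" %in% measures) {
      mod <- if (all(fc$thresholded == 0)) list(Q_w = 0, membership = NULL)
             else modularity_consensus(fc, runs = louvain_runs, seed = seed)
      out$Q_w <- mod$Q_w
      out$membership <- mod$membership
    }
  }
  out
}
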