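#' Jansen-Rit population parameters
#'
#' Defaults are the classic Jansen-Rit values except the inhibitory-to-
#' pyramidal constant C4 = 0.5 C (instead of 0.25 C), which widens the range
#' of coupling values sustaining oscillations. Units: PSP amplitudes A, B in
#' mV; inverse time constants a, b, a_bar in 1/s; sigmoid slopes r1, r2 in
#' 1/mV; zeta_max in 1/s; nu_th in mV.
#'
#' @param A,B excitatory / inhibitory PSP amplitude (mV).
#' @param a,b excitatory / inhibitory inverse time constants (1/s).
#' @param a_bar long-range EPSP inverse time constant (1/s, default 0.5 a:
#'   long-range inputs on apical dendrites are slower at the soma).
#' @param C intra-area connectivity constant; C1..C4 derive from it.
#' @param C1,C2,C3,C4 population coupling constants.
#' @param zeta_max maximum population firing rate (1/s).
#' @param nu_th PSP of half-maximal response (mV).
#' @param r1,r2 sigmoid slopes of excitatory / inhibitory interneurons (1/mV).
#' @return A list of class `jr_params`.
#' @export
jr_params <- function(A = 3.25, B = 22, a = 100, b = 50, a_bar = 0.5 * a,
                      C = 135, C1 = C, C2 = 0.8 * C, C3 = 0.25 * C,
                      C4 = 0.5 * C, zeta_max = 5, nu_th = 6,
                      r1 = 0.56, r2 = 0.56) {
  p <- list(A = A, B = B, a = a, b = b, a_bar = a_bar, C = C, C1 = C1,
            C2 = C2, C3 = C3, C4 = C4, zeta_max = zeta_max, nu_th = nu_th,
            r1 = r1, r2 = r2)
  if (any(unlist(p) <= 0)) stop("all Jansen-Rit parameters must be positive")
  structure(p, class = "jr_params")
}

#' Population sigmoid (PSP to firing rate)
#'
#' S(nu, r) = zeta_max / (1 + exp(r (nu_th - nu))): strictly increasing,
#' bounded in (0, zeta_max), half-maximal at nu_th. Overflow-safe.
#'
#' @param nu membrane potential (mV), vectorized.
#' @param r sigmoid slope (1/mV).
#' @param params a [jr_params].
#' @return Firing rate(s) in 1/s.
#' @export
jr_sigmoid <- function(nu, r, params = jr_params()) {
  ex <- pmin(pmax(r * (params$nu_th - nu), -500), 500)
  params$zeta_max / (1 + exp(ex))
}

#' Gaussian input specification
#'
#' Pyramidal populations receive an external input p(t) ~ N(mu, sigma^2)
#' (impulses/s), redrawn each integration step and held constant over the
#' step (piecewise-constant sampled input, the convention under which the
#' stated sigma = 2 keeps the noise comparable to the intrinsic dynamics).
#'
#' @param mu mean input (impulses/s, default 2).
#' @param sigma input standard deviation (impulses/s, default 2).
#' @param seed integer RNG seed for the simulation.
#' @return A list of class `noise_spec`.
#' @export
noise_spec <- function(mu = 2, sigma = 2, seed = 1) {
  if (sigma < 0) stop("sigma must be >= 0")
  structure(list(mu = mu, sigma = sigma, seed = seed), class = "noise_spec")
}

#' Per-node gain map
#'
#' Holds the per-node pyramidal sigmoid slope r0 (filter gain, the
#' noradrenergic proxy) and the global coupling alpha (cholinergic-like
#' excitability scaling all long-range inputs).
#'
#' @param r0 per-node slope(s) (1/mV); scalar is recycled at simulation time.
#' @param alpha global coupling (>= 0).
#' @return A list of class `gain_map`.
#' @export
gain_map <- function(r0, alpha) {
  if (any(r0 < 0) || alpha < 0) stop("r0 and alpha must be >= 0")
  structure(list(r0 = r0, alpha = alpha), class = "gain_map")
}

#' Build a gain map with a modulated node subset
#'
#' All nodes get `base_r0` except `targets`, which get `target_r0`.
#'
#' @param n node count.
#' @param alpha global coupling.
#' @param base_r0 baseline slope (1/mV).
#' @param targets integer node indices to modulate (may be empty).
#' @param target_r0 slope assigned to the targets.
#' @return A [gain_map] with an r0 vector of length n.
#' @export
make_gain_map <- function(n, alpha, base_r0, targets = integer(0),
                          target_r0 = base_r0) {
  targets <- as.integer(targets)
  if (anyDuplicated(targets)) stop("duplicate target nodes")
  if (length(targets) && (min(targets) < 1 || max(targets) > n))
    stop("target index out of range")
  r0 <- rep(base_r0, n)
  r0[targets] <- target_r0
  gain_map(r0, alpha)
}

#' Simulation configuration
#'
#' @param dt integration step (s, default 0.001).
#' @param duration total simulated time (s, default 660: the equivalent of
#'   11 min of recording).
#' @param discard initial transient removed (s, default 60).
#' @param params a [jr_params].
#' @param gain a [gain_map].
#' @param noise a [noise_spec].
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(dt = 0.001, duration = 660, discard = 60,
                       params = jr_params(), gain = gain_map(0.56, 0),
                       noise = noise_spec()) {
  if (dt <= 0) stop("dt must be positive")
  if (discard >= duration) stop("discard must be shorter than duration")
  structure(list(dt = dt, duration = duration, discard = discard,
                 params = params, gain = gain, noise = noise),
            class = "sim_config")
}

#' Number of retained samples implied by a configuration
#'
#' @param config a [sim_config].
#' @return Integer: round(duration/dt) - round(discard/dt).
#' @export
n_retained_samples <- function(config) {
  round(config$duration / config$dt) - round(config$discard / config$dt)
}

#' Simulate the stochastic Jansen-Rit network
#'
#' Integrates the 8-equation-per-node system by Euler-Maruyama at `dt`,
#' coupling nodes through the normalized connectome
#' (z_i = sum_j W_ij x3_j, scaled by C * alpha inside the pyramidal input),
#' from a zero initial state. The EEG-like potential is
#' nu_i = C2 x1_i - C4 x2_i + C alpha z_i and the pyramidal firing rate is
#' zeta_i = S(nu_i, r0_i). The first `discard` seconds are removed.
#' Reproducible bit-for-bit under the noise seed.
#'
#' @param Mn a [normalize_connectome] result (or a plain matrix already
#'   normalized; a raw `connectome` is rejected to avoid silent mis-scaling).
#' @param config a [sim_config].
#' @return An object of class `neural_trace`: list with `nu` (n x T, mV),
#'   `zeta` (n x T, 1/s), `rate` (Hz), `config`.
#' @export
simulate_jr <- function(Mn, config = sim_config()) {
  if (inherits(Mn, "normalized_connectome")) {
    W <- Mn$weights
  } else if (is.matrix(Mn)) {
    W <- Mn
  } else if (inherits(Mn, "connectome")) {
    stop("pass a normalized connectome (see normalize_connectome())")
  } else stop("Mn must be a normalized connectome or matrix")
  n <- nrow(W)
  r0 <- config$gain$r0
  if (length(r0) == 1) r0 <- rep(r0, n)
  if (length(r0) != n) stop("gain map length != node count")
  n_steps <- round(config$duration / config$dt)
  n_discard <- round(config$discard / config$dt)
  res <- with_seed(config$noise$seed,
                   jr_integrate_cpp(W, r0, config$gain$alpha,
                                    unclass(config$params),
                                    config$noise$mu, config$noise$sigma,
                                    config$dt, n_steps, n_discard))
  structure(list(nu = res$nu, zeta = res$zeta, rate = 1 / config$dt,
                 config = config),
            class = "neural_trace")
}

#' @export
print.neural_trace <- function(x, ...) {
  cat(sprintf("<neural_trace> %d nodes x %d samples at %g Hz (%.1f s retained)\n",
              nrow(x$nu), ncol(x$nu), x$rate, ncol(x$nu) / x$rate))
  invisible(x)
}
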