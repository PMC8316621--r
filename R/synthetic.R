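#' Generate a synthetic connectome with planted modules and a rich-club core
#'
#' Emulates the statistical structure of a human-style structural matrix:
#' symmetric, zero diagonal, weights in [0, 1], ~40% connection density,
#' heavy-tailed (log-normal) weights, balanced modules, and a hub core drawn
#' across modules. Core-core edges are near-complete and carry `core_boost`
#' times stronger weights, while core-periphery weights are mildly damped
#' (`cp_damp`): the club's mutual weights then exceed what the strength
#' sequence alone implies, which is what makes a weighted rich club
#' detectable against a degree- and strength-preserving null.
#'
#' The realized edge count is fixed at `round(density * n(n-1)/2)` (edges are
#' sampled without replacement with modular/core propensities), so the
#' realized density matches the target up to rounding.
#'
#' @param n node count (default 90).
#' @param n_modules number of modules (default 4).
#' @param hub_fraction fraction of nodes in the hub core (default 0.2).
#' @param density target edge density (default 0.40).
#' @param weight_meanlog,weight_sdlog log-normal weight law parameters
#'   (defaults -2.8, 1.1, strongly heavy-tailed as in empirical structural matrices); weights are clipped to [0, 1].
#' @param core_boost multiplicative weight factor for core-core edges
#'   (default 3). `core_boost = 1` disables planting altogether and returns a
#'   modular Erdos-Renyi-like graph with a homogeneous weight law (no club).
#' @param cp_damp multiplicative damping of core-periphery weights
#'   (default 0.7; ignored when core_boost = 1).
#' @param seed integer RNG seed (generation is reproducible under it).
#' @return A [connectome] with attributes `core` (planted core node indices)
#'   and `module` (per-node module id).
#' @export
generate_connectome <- function(n = 90, n_modules = 4, hub_fraction = 0.2,
                                density = 0.40, weight_meanlog = -2.8,
                                weight_sdlog = 1.1, core_boost = 3,
                                cp_damp = 0.7, seed = 1) {
  if (density <= 0 || density > 1) stop("density must be in (0, 1]")
  n_core <- round(hub_fraction * n)
  if (n_core < 3) stop("hub_fraction * n must be >= 3")
  n_pairs <- n * (n - 1) / 2
  m <- round(density * n_pairs)
  if (m < n - 1) stop("density infeasible: too few edges for n")

  module <- rep_len(seq_len(n_modules), n)
  # hub core spread across modules so feeders exist everywhere
  core <- integer(0)
  for (mod in seq_len(n_modules)) {
    take <- which(module == mod)
    core <- c(core, head(take, ceiling(n_core / n_modules)))
  }
  core <- sort(head(core, n_core))
  periph <- setdiff(seq_len(n), core)

  if (core_boost == 1) {
    # no club planted: modular Erdos-Renyi-like graph, homogeneous weight law
    W <- with_seed(seed, {
      ij <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
      prop <- ifelse(module[ij[, 1]] == module[ij[, 2]], 2, 1)
      sel <- sample.int(n_pairs, m, prob = prop)
      w <- pmin(rlnorm(m, weight_meanlog, weight_sdlog), 1)
      W <- matrix(0, n, n)
      W[ij[sel, , drop = FALSE]] <- w
      W[ij[sel, c(2, 1), drop = FALSE]] <- w
      W
    })
    out <- connectome(W)
    attr(out, "core") <- integer(0)
    attr(out, "module") <- module
    return(out)
  }

  W <- with_seed(seed, {
    # (1) complete core: every core-core pair connected (the planted club)
    cc_edges <- t(utils::combn(core, 2))
    # (2) core-periphery: every core node gets the same periphery partner
    #     count, sized so the shared core degree sits just above the
    #     periphery degree ceiling -- the planted club is crisply defined
    mean_deg <- 2 * m / n
    margin <- ceiling(2 * sqrt(mean_deg)) # above the periphery degree ceiling
    d_cp <- rep(min(length(periph),
                    max(0, round(mean_deg - n_core + margin))), n_core)
    cp_edges <- do.call(rbind, lapply(seq_len(n_core), function(k)
      cbind(core[k], sample(periph, d_cp[k]))))
    # (3) periphery-periphery fills up to the exact target edge count,
    #     with modular preference
    m_pp <- m - nrow(cc_edges) - nrow(cp_edges)
    if (m_pp < 0) stop("density infeasible: core edges exceed target count")
    pp_pairs <- t(utils::combn(periph, 2))
    prop <- ifelse(module[pp_pairs[, 1]] == module[pp_pairs[, 2]], 2, 1)
    if (m_pp > nrow(pp_pairs)) stop("density infeasible for n")
    sel <- sample.int(nrow(pp_pairs), m_pp, prob = prop)
    edges <- rbind(cc_edges, cp_edges, pp_pairs[sel, , drop = FALSE])
    kind <- rep(c("cc", "cp", "pp"),
                c(nrow(cc_edges), nrow(cp_edges), m_pp))
    w <- pmin(rlnorm(nrow(edges), weight_meanlog, weight_sdlog), 1)
    boost <- ifelse(kind == "cc", core_boost,
                    ifelse(kind == "cp" & core_boost > 1, cp_damp, 1))
    w <- pmin(w * boost, 1)
    W <- matrix(0, n, n)
    W[edges] <- w
    W[edges[, c(2, 1)]] <- w
    W
  })
  out <- connectome(W)
  attr(out, "core") <- core
  attr(out, "module") <- module
  out
}

#' Generate fixture signal sets for testing functional measures
#'
#' @param kind one of `"coherent"` (identical 10 Hz sinusoids), `"antiphase"`
#'   (half the nodes shifted by pi), `"independent_noise"` (white Gaussian),
#'   `"block_correlated"` (two blocks sharing slow signals, weak noise).
#' @param n number of channels.
#' @param T number of samples.
#' @param rate sampling rate (Hz).
#' @param seed integer RNG seed.
#' @return An object of class `fixture_signals`: list with `traces` (n x T),
#'   `rate`, `kind`, and for block_correlated a `block` attribute.
#' @export
generate_fixture_signals <- function(kind, n, T, rate, seed = 1) {
  kind <- match.arg(kind, c("coherent", "antiphase", "independent_noise",
                            "block_correlated"))
  tt <- (seq_len(T) - 1) / rate
  traces <- with_seed(seed, switch(
    kind,
    coherent = matrix(rep(sin(2 * pi * 10 * tt), each = n), n, T, byrow = FALSE),
    antiphase = {
      ph <- rep(c(0, pi), length.out = n)
      t(vapply(ph, function(p) sin(2 * pi * 10 * tt + p), numeric(T)))
    },
    independent_noise = matrix(rnorm(n * T), n, T),
    block_correlated = {
      block <- rep(1:2, each = ceiling(n / 2), length.out = n)
      base <- vapply(1:2, function(b) {
        f <- runif(3, 0.02, 0.05)
        ph <- runif(3, 0, 2 * pi)
        rowSums(vapply(1:3, function(k) sin(2 * pi * f[k] * tt + ph[k]),
                       numeric(T)))
      }, numeric(T))
      sig <- t(base[, block]) + 0.2 * matrix(rnorm(n * T), n, T)
      attr(sig, "block") <- block
      sig
    }))
  block <- attr(traces, "block")
  attr(traces, "block") <- NULL
  structure(list(traces = traces, rate = rate, kind = kind, block = block),
            class = "fixture_signals")
}
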