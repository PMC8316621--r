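# Brute-force oracles, deliberately independent of the package internals
# (no igraph, no shared code paths).

# all-pairs shortest paths on lengths 1/w via Floyd-Warshall
oracle_distances <- function(W) {
  n <- nrow(W)
  d <- matrix(Inf, n, n)
  diag(d) <- 0
  for (i in seq_len(n)) for (j in seq_len(n))
    if (i != j && W[i, j] > 0) d[i, j] <- 1 / W[i, j]
  for (k in seq_len(n)) for (i in seq_len(n)) for (j in seq_len(n))
    if (d[i, k] + d[k, j] < d[i, j]) d[i, j] <- d[i, k] + d[k, j]
  d
}

oracle_nodal_efficiency <- function(W) {
  n <- nrow(W)
  d <- oracle_distances(W)
  inv <- 1 / d
  inv[!is.finite(inv)] <- 0
  diag(inv) <- 0
  rowSums(inv) / (n - 1)
}

oracle_global_efficiency <- function(W) {
  n <- nrow(W)
  sum_inv <- sum({
    d <- oracle_distances(W)
    inv <- 1 / d
    inv[!is.finite(inv)] <- 0
    diag(inv) <- 0
    inv
  })
  sum_inv / (n * (n - 1))
}

# triangle intensity by explicit triple loop
oracle_triangles <- function(W) {
  n <- nrow(W)
  t_i <- numeric(n)
  for (i in seq_len(n)) {
    acc <- 0
    for (j in seq_len(n)) for (h in seq_len(n)) {
      if (j == i || h == i || j == h) next
      acc <- acc + (W[i, j] * W[i, h] * W[j, h])^(1 / 3)
    }
    t_i[i] <- acc / 2
  }
  t_i
}

oracle_clustering <- function(W) {
  t_i <- oracle_triangles(W)
  k <- rowSums(W > 0)
  ifelse(k > 1, 2 * t_i / (k * (k - 1)), 0)
}

# s-core membership at level s by literal recursive shell removal
oracle_s_core_members <- function(W, s) {
  remaining <- rep(TRUE, nrow(W))
  repeat {
    if (!any(remaining)) break
    str <- rowSums(W[, remaining, drop = FALSE])
    str[!remaining] <- Inf
    bad <- remaining & str < s
    if (!any(bad)) break
    remaining[bad] <- FALSE
  }
  remaining
}

# critical s per node: max candidate s at which the node survives, with the
# candidate set taken exhaustively from the strengths of every induced
# subgraph (feasible for small n)
oracle_critical_s <- function(W) {
  n <- nrow(W)
  stopifnot(n <= 12)
  cand <- 0
  for (mask in seq_len(2^n) - 1) {
    keep <- as.logical(bitwAnd(mask, 2^(seq_len(n) - 1)))
    if (sum(keep) < 1) next
    cand <- c(cand, rowSums(W[keep, keep, drop = FALSE]))
  }
  cand <- sort(unique(cand))
  crit <- numeric(n)
  for (s in cand) {
    mem <- oracle_s_core_members(W, s)
    crit[mem] <- s
  }
  crit
}

# random small test graph (connected-ish, weighted, symmetric)
random_graph <- function(n, density = 0.5, seed = 1) {
  set.seed(seed)
  W <- matrix(0, n, n)
  ut <- which(upper.tri(W))
  on <- ut[runif(length(ut)) < density]
  W[on] <- runif(length(on), 0.05, 1)
  W <- W + t(W)
  W
}

# reference Jansen-Rit integration in plain R (Euler, deterministic only)
oracle_jr_deterministic <- function(W, r0, alpha, p, mu, dt, n_steps) {
  n <- nrow(W)
  S <- function(v, r) p$zeta_max / (1 + exp(pmin(pmax(r * (p$nu_th - v), -500), 500)))
  x0 <- x1 <- x2 <- x3 <- y0 <- y1 <- y2 <- y3 <- numeric(n)
  nu_hist <- matrix(0, n, n_steps)
  for (t in seq_len(n_steps)) {
    z <- as.numeric(W %*% x3)
    nu <- p$C2 * x1 - p$C4 * x2 + p$C * alpha * z
    nu_hist[, t] <- nu
    Sp <- S(nu, r0)
    dy0 <- p$A * p$a * Sp - 2 * p$a * y0 - p$a^2 * x0
    dy1 <- p$A * p$a * (mu + S(p$C1 * x0, p$r1)) - 2 * p$a * y1 - p$a^2 * x1
    dy2 <- p$B * p$b * S(p$C3 * x0, p$r2) - 2 * p$b * y2 - p$b^2 * x2
    dy3 <- p$A * p$a_bar * Sp - 2 * p$a_bar * y3 - p$a_bar^2 * x3
    x0 <- x0 + dt * y0; x1 <- x1 + dt * y1
    x2 <- x2 + dt * y2; x3 <- x3 + dt * y3
    y0 <- y0 + dt * dy0; y1 <- y1 + dt * dy1
    y2 <- y2 + dt * dy2; y3 <- y3 + dt * dy3
  }
  nu_hist
}

# small planted-club toy: 4-node heavy complete core + 8-node weak ring with
# a couple of core attachments per periphery node
toy_planted_club <- function() {
  n <- 12
  W <- matrix(0, n, n)
  core <- 1:4
  for (i in core) for (j in core) if (i < j) W[i, j] <- 0.9
  per <- 5:12
  for (k in seq_along(per)) {
    i <- per[k]
    j <- per[if (k == length(per)) 1 else k + 1]
    W[min(i, j), max(i, j)] <- 0.1
  }
  # each periphery node touches two core nodes (keeps core degree on top)
  for (k in seq_along(per)) {
    W[(k - 1) %% 4 + 1, per[k]] <- 0.1
    W[k %% 4 + 1, per[k]] <- 0.1
  }
  W <- W + t(W)
  connectome(W)
}
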