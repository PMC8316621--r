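test_that("phase synchrony hits the closed-form fixtures", {
  co <- generate_fixture_signals("coherent", n = 90, T = 10000, rate = 1000)
  ps <- phase_synchrony(co)
  expect_equal(ps$R_bar, 1, tolerance = 1e-6)

  an <- generate_fixture_signals("antiphase", n = 2, T = 10000, rate = 1000)
  expect_lt(phase_synchrony(an)$R_bar, 0.01)

  no <- generate_fixture_signals("independent_noise", n = 90, T = 10000,
                                 rate = 1000, seed = 4)
  expect_lt(phase_synchrony(no)$R_bar, 0.2)

  # R_bar invariant to a common phase shift of all channels
  tt <- (seq_len(10000) - 1) / 1000
  sh <- matrix(rep(sin(2 * pi * 10 * tt + 0.7), each = 90), 90)
  expect_equal(phase_synchrony(sh, rate = 1000)$R_bar, ps$R_bar,
               tolerance = 1e-6)

  # flat channel errors, naming the node
  bad <- co$traces
  bad[3, ] <- 1
  expect_error(phase_synchrony(bad, rate = 1000), "node 3")
})

test_that("FT surrogates preserve per-channel amplitude spectra exactly", {
  set.seed(9)
  x <- rnorm(512)
  xs <- gainsweep:::ft_surrogate(x)
  expect_lt(max(abs(Mod(fft(xs)) - Mod(fft(x))) / max(Mod(fft(x)))), 1e-6)
  # and destroys cross-correlation of duplicated channels
  y <- rbind(x, x)
  ys <- t(apply(y, 1, function(r) gainsweep:::ft_surrogate(r)))
  expect_lt(abs(cor(ys[1, ], ys[2, ])), 0.5)
})

test_that("fc_threshold keeps true edges and controls false positives", {
  set.seed(2)
  n <- 20
  T <- 300
  x <- matrix(rnorm(n * T), n, T)
  x[2, ] <- x[1, ] + 1e-6 * rnorm(T) # duplicated pair
  fc <- fc_threshold(x, n_surrogates = 200, seed = 5)
  expect_gt(fc$thresholded[1, 2], 0.99)
  noise_pairs <- upper.tri(fc$thresholded)
  noise_pairs[1, 2] <- FALSE
  expect_gte(mean(fc$thresholded[noise_pairs] == 0), 0.95)
  # symmetric with zero diagonal
  expect_true(isSymmetric(fc$thresholded))
  expect_true(all(diag(fc$thresholded) == 0))
  expect_true(all(fc$thresholded >= 0))
  expect_error(fc_threshold(rbind(rep(1, 50), rnorm(50))), "constant")
})

test_that("FDR keeps the retained-edge fraction at or below q on null data", {
  fracs <- vapply(1:10, function(s) {
    x <- generate_fixture_signals("independent_noise", n = 16, T = 250,
                                  rate = 0.5, seed = 100 + s)$traces
    fc <- fc_threshold(x, n_surrogates = 150, q = 0.05, seed = s)
    mean(fc$thresholded[upper.tri(fc$thresholded)] > 0)
  }, numeric(1))
  # binomial slack: mean over 10 seeds within ~2 se of q
  expect_lte(mean(fracs), 0.05 + 2 * sd(fracs) / sqrt(10) + 0.01)
})

test_that("global efficiency matches hand enumeration and oracles", {
  expect_equal(global_efficiency(matrix(1, 4, 4) - diag(4)), 1)
  expect_equal(global_efficiency(matrix(0, 5, 5)), 0)
  # 3-node chain, unit weights: distances 1, 1, 2 -> E = 5/6
  W <- matrix(0, 3, 3)
  W[1, 2] <- W[2, 1] <- 1
  W[2, 3] <- W[3, 2] <- 1
  expect_equal(global_efficiency(W), 5 / 6)
  for (seed in 1:5) {
    Wr <- random_graph(8, seed = 30 + seed)
    expect_equal(global_efficiency(Wr), oracle_global_efficiency(Wr),
                 tolerance = 1e-10)
  }
})

test_that("consensus modularity recovers planted communities", {
  # two disconnected 4-cliques: Q = 0.5 exactly, two modules
  W <- matrix(0, 8, 8)
  W[1:4, 1:4] <- 1
  W[5:8, 5:8] <- 1
  diag(W) <- 0
  mod <- modularity_consensus(W, seed = 1, runs = 50)
  expect_equal(mod$Q_w, 0.5)
  expect_equal(mod$n_modules, 2)
  expect_length(unique(mod$membership[1:4]), 1)

  # complete homogeneous graph: no structure
  K <- matrix(1, 10, 10) - diag(10)
  modK <- modularity_consensus(K, seed = 1, runs = 50)
  expect_lte(modK$Q_w, 0.05)

  # deterministic under a fixed seed
  mod2 <- modularity_consensus(W, seed = 1, runs = 50)
  expect_identical(mod$membership, mod2$membership)

  expect_error(modularity_consensus(matrix(0, 4, 4)), "empty")
})

test_that("block-correlated fixtures yield two modules through the pipeline", {
  bl <- generate_fixture_signals("block_correlated", n = 20, T = 300,
                                 rate = 0.5, seed = 7)
  fc <- fc_threshold(bl, n_surrogates = 150, seed = 3)
  mod <- modularity_consensus(fc, seed = 4, runs = 100)
  expect_equal(mod$n_modules, 2)
  expect_equal(unname(lengths(split(seq_len(20), mod$membership))),
               unname(lengths(split(seq_len(20), bl$block))))
})

test_that("FCD windowing, bounds and distances behave as specified", {
  # 600 s at 0.5 Hz: 100 s windows, 2 s steps -> 251 windows
  bl <- generate_fixture_signals("block_correlated", n = 10, T = 300,
                                 rate = 0.5, seed = 2)
  fd <- fcd(bl$traces, rate = 0.5)
  expect_equal(fd$n_windows, 251)
  expect_equal(dim(fd$values), c(251, 251))
  expect_true(all(fd$values >= 0 & fd$values <= 1))
  expect_true(all(diag(fd$values) == 0))
  expect_true(isSymmetric(fd$values))

  # statically correlated signals: all distances small
  set.seed(11)
  base <- rnorm(300)
  x <- rbind(base + 0.05 * rnorm(300),
             base + 0.05 * rnorm(300),
             -base + 0.05 * rnorm(300),
             base + 0.05 * rnorm(300))
  fd2 <- fcd(x, rate = 0.5)
  expect_lt(max(fd2$values), 0.05)

  # orthogonal unit FC vectors give the Clarkson distance sqrt(2)/2
  expect_equal(gainsweep:::clarkson_distance(c(1, 0, 0), c(0, 0, 1)),
               sqrt(2) / 2)
  expect_equal(gainsweep:::clarkson_distance(c(2, 0), c(4, 0)), 0)

  expect_error(fcd(matrix(rnorm(40), 2), rate = 0.5, window = 100),
               "shorter")
})
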