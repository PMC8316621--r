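test_that("population sigmoid matches closed forms and is well-behaved", {
  p <- jr_params()
  # half-maximal response at nu_th (zeta_max = 5)
  expect_equal(jr_sigmoid(6, 0.56, p), 2.5)
  expect_equal(jr_sigmoid(6, 2, p), 2.5)
  # saturation at zeta_max
  expect_equal(jr_sigmoid(1e6, 0.56, p), 5)
  expect_equal(jr_sigmoid(-1e6, 0.56, p), 0)
  # direct evaluation at rest: 5 / (1 + exp(3.36))
  expect_equal(jr_sigmoid(0, 0.56, p), 5 / (1 + exp(3.36)), tolerance = 1e-12)
  # strictly increasing, overflow-safe
  v <- seq(-1e4, 1e4, length.out = 101)
  expect_true(all(diff(jr_sigmoid(v, 0.56, p)) >= 0))
  expect_true(all(is.finite(jr_sigmoid(c(-1e308, 1e308), 0.56, p))))
})

test_that("configuration arithmetic and gain maps follow the contract", {
  cfg <- sim_config()
  expect_equal(cfg$duration, 660)
  expect_equal(cfg$discard, 60)
  expect_equal(n_retained_samples(cfg), 600000)
  expect_error(sim_config(duration = 30, discard = 60), "shorter")

  gm <- make_gain_map(10, 0.65, 0.33, targets = c(2, 5), target_r0 = 0.67)
  expect_equal(gm$r0, c(0.33, 0.67, 0.33, 0.33, 0.67, rep(0.33, 5)))
  expect_equal(make_gain_map(5, 0.5, 0.33)$r0, rep(0.33, 5))
  expect_equal(make_gain_map(5, 0.5, 0.33, targets = 1:5, 0.67)$r0,
               rep(0.67, 5))
  expect_error(make_gain_map(5, 0.5, 0.33, targets = c(2, 2), 0.5), "duplicate")
  expect_error(make_gain_map(5, 0.5, 0.33, targets = 9, 0.5), "range")
})

test_that("simulation is reproducible, bounded and has the right shape", {
  M <- generate_connectome(n = 12, n_modules = 2, hub_fraction = 0.3, seed = 2)
  Mn <- normalize_connectome(M)
  cfg <- sim_config(duration = 8, discard = 2, gain = gain_map(0.4, 0.5),
                    noise = noise_spec(seed = 7))
  tr1 <- simulate_jr(Mn, cfg)
  expect_equal(dim(tr1$nu), c(12, 6000))
  expect_equal(n_retained_samples(cfg), 6000)
  # zeta within [0, zeta_max], everything finite
  expect_true(all(is.finite(tr1$nu)))
  expect_true(all(tr1$zeta >= 0 & tr1$zeta <= 5))
  # bit-identical replay under the same seed
  tr2 <- simulate_jr(Mn, cfg)
  expect_identical(tr1$nu, tr2$nu)
  # different seed, different trajectory
  cfg3 <- sim_config(duration = 8, discard = 2, gain = gain_map(0.4, 0.5),
                     noise = noise_spec(seed = 8))
  expect_false(identical(simulate_jr(Mn, cfg3)$nu, tr1$nu))
  # raw connectome is rejected
  expect_error(simulate_jr(M, cfg), "normalized")
  # gain map length mismatch
  bad <- sim_config(duration = 4, discard = 1,
                    gain = gain_map(rep(0.4, 5), 0.5))
  expect_error(simulate_jr(Mn, bad), "length")
})

test_that("noise- and coupling-free dynamics settle to a fixed point", {
  W <- matrix(0, 2, 2)
  cfg <- sim_config(duration = 10, discard = 0, gain = gain_map(0.33, 0),
                    noise = noise_spec(mu = 0, sigma = 0))
  tr <- simulate_jr(W, cfg)
  # |d nu / dt| < 1e-6 mV/ms within 5 s
  late <- tr$nu[1, 5001:10000]
  expect_lt(max(abs(diff(late))), 1e-6)
})

test_that("integrator agrees with an independent R reference", {
  p <- jr_params()
  W <- matrix(0, 2, 2)
  W[1, 2] <- W[2, 1] <- 0.8
  # deterministic coupled regime
  cfg <- sim_config(duration = 10, discard = 0, gain = gain_map(0.56, 0.3),
                    noise = noise_spec(mu = 2, sigma = 0))
  tr <- simulate_jr(W, cfg)
  ref <- oracle_jr_deterministic(W, rep(0.56, 2), 0.3, p, mu = 2,
                                 dt = 0.001, n_steps = 10000)
  # same scheme, independent implementation: should agree to rounding
  expect_lt(sqrt(mean((tr$nu - ref)^2)), 1e-8)
  # dt-refinement, noise and coupling off: a dt/10 reference stays within
  # 1e-3 mV RMS on the retained traces (the 1 s discard absorbs the sharp
  # onset transient, where forward-Euler solutions at different steps
  # legitimately differ by ~dt)
  W0 <- matrix(0, 2, 2)
  cfg0 <- sim_config(duration = 10, discard = 1, gain = gain_map(0.56, 0),
                     noise = noise_spec(mu = 2, sigma = 0))
  tr0 <- simulate_jr(W0, cfg0)
  ref10 <- oracle_jr_deterministic(W0, rep(0.56, 2), 0, p, mu = 2,
                                   dt = 0.0001, n_steps = 100000)
  ref10 <- ref10[, seq(1, 100000, by = 10), drop = FALSE][, 1001:10000]
  expect_lt(sqrt(mean((tr0$nu - ref10)^2)), 1e-3)
})

test_that("raising the gain uniformly raises phase synchrony", {
  M <- generate_connectome(seed = 3)
  Mn <- normalize_connectome(M)
  rb <- vapply(c(0.33, 0.67), function(r0) {
    mean(vapply(1:2, function(s) {
      cfg <- sim_config(duration = 40, discard = 10,
                        gain = gain_map(r0, 0.65),
                        noise = noise_spec(seed = s))
      phase_synchrony(simulate_jr(Mn, cfg))$R_bar
    }, numeric(1)))
  }, numeric(1))
  expect_gt(rb[2], rb[1])
})
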