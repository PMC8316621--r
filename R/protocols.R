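# Experiment protocols: uniform parameter sweeps, incremental neuromodulation
# guided by local node metrics, and fixed-size subset neuromodulation guided
# by meso-scale categories, each summarized by areas under the curve.

# one pipeline evaluation: simulate on the normalized connectome and summarize
run_condition <- function(Mn, alpha, r0, seed, duration, discard,
                          measures, fc_surrogates, louvain_runs) {
  n <- Mn$n
  r0 <- if (length(r0) == 1) rep(r0, n) else r0
  cfg <- sim_config(duration = duration, discard = discard,
                    gain = gain_map(r0, alpha),
                    noise = noise_spec(seed = seed))
  trace <- simulate_jr(Mn, cfg)
  functional_summary(trace, seed = seed, measures = measures,
                     fc_surrogates = fc_surrogates,
                     louvain_runs = louvain_runs)
}

#' Trapezoidal area under a curve
#'
#' @param x ordinates (strictly increasing).
#' @param y values at `x`.
#' @return Scalar AUC.
#' @export
auc_trapezoid <- function(x, y) {
  o <- order(x)
  x <- x[o]; y <- y[o]
  sum(diff(x) * (head(y, -1) + tail(y, -1)) / 2)
}

#' Compare two AUC samples with an independent-samples t-test
#'
#' @param a,b numeric vectors (>= 2 values each).
#' @return List with `difference` (mean(a) - mean(b)) and `p_value`
#'   (two-sided, pooled-variance Student's t).
#' @export
compare_auc <- function(a, b) {
  if (length(a) < 2 || length(b) < 2) stop("need >= 2 samples per group")
  if (sd(a) == 0 && sd(b) == 0) {
    if (mean(a) == mean(b)) return(list(difference = 0, p_value = 1))
    stop("zero variance in both groups with unequal means")
  }
  tt <- t.test(a, b, var.equal = TRUE)
  list(difference = mean(a) - mean(b), p_value = tt$p.value)
}

#' Uniform (alpha, r0) parameter sweep
#'
#' Simulates every grid combination with identical parameters at all nodes
#' and returns seed-averaged grids of phase synchrony, global efficiency and
#' modularity. The connectome is normalized internally (surrogate matrices
#' included, so each matrix is simulated on its own mean-strength scale).
#'
#' @param M a [connectome].
#' @param alpha_grid,r0_grid parameter vectors in [0, 1].
#' @param seeds integer vector of realization seeds.
#' @param duration,discard simulated time and transient (s).
#' @param measures which measures to compute (see [functional_summary]).
#' @param fc_surrogates,louvain_runs analysis settings.
#' @return An object of class `sweep_result`: list of grids
#'   (`R_bar`, `E_w`, `Q_w`: alpha x r0, seed means), the grids, seeds.
#' @export
uniform_sweep <- function(M, alpha_grid, r0_grid, seeds = 1:3,
                          duration = 660, discard = 60,
                          measures = c("R_bar", "E_w", "Q_w"),
                          fc_surrogates = 500, louvain_runs = 200) {
  if (any(alpha_grid < 0 | alpha_grid > 1) || any(r0_grid < 0 | r0_grid > 1))
    stop("grids must lie in [0, 1]")
  Mn <- normalize_connectome(M)
  dims <- c(length(alpha_grid), length(r0_grid))
  acc <- list(R_bar = array(0, dims), E_w = array(0, dims), Q_w = array(0, dims))
  for (ia in seq_along(alpha_grid)) for (ir in seq_along(r0_grid)) {
    vals <- lapply(seeds, function(s) {
      tryCatch(
        run_condition(Mn, alpha_grid[ia], r0_grid[ir], s, duration, discard,
                      measures, fc_surrogates, louvain_runs),
        error = function(e) stop(sprintf(
          "sweep failed at alpha=%.3g, r0=%.3g, seed=%d: %s",
          alpha_grid[ia], r0_grid[ir], s, conditionMessage(e))))
    })
    for (m in c("R_bar", "E_w", "Q_w"))
      acc[[m]][ia, ir] <- mean(vapply(vals, `[[`, numeric(1), m))
  }
  structure(list(alpha_grid = alpha_grid, r0_grid = r0_grid,
                 R_bar = acc$R_bar, E_w = acc$E_w, Q_w = acc$Q_w,
                 n_realizations = length(seeds), seeds = seeds),
            class = "sweep_result")
}

#' Incremental neuromodulation ranked by a local node metric
#'
#' Ranks nodes by strength, nodal efficiency or clustering (or permutes them
#' for `direction = "random"`), then raises r0 from `base_r0` to `target_r0`
#' in the top-k nodes for k over `counts`, simulating each condition per
#' seed. AUCs are trapezoids over the modulated-node count.
#'
#' @param M a [connectome].
#' @param metric_name one of "strength", "nodal_efficiency", "clustering".
#' @param direction "high_to_low", "low_to_high" or "random".
#' @param base_r0,target_r0 baseline and target sigmoid slopes.
#' @param alpha global coupling (default 0.65).
#' @param seeds realization seeds.
#' @param counts modulated-node counts (default seq(0, n, by = 3)).
#' @param duration,discard simulated time and transient (s).
#' @param measures,fc_surrogates,louvain_runs analysis settings.
#' @return An object of class `incremental_result`: `curves` is a data.frame
#'   (count, seed, R_bar, E_w, Q_w); `auc` a per-measure, per-seed matrix.
#' @export
incremental_neuromod <- function(M, metric_name = "strength",
                                 direction = c("high_to_low", "low_to_high",
                                               "random"),
                                 base_r0 = 0.33, target_r0 = 0.67,
                                 alpha = 0.65, seeds = 1:3, counts = NULL,
                                 duration = 660, discard = 60,
                                 measures = c("R_bar", "E_w", "Q_w"),
                                 fc_surrogates = 500, louvain_runs = 200) {
  direction <- match.arg(direction)
  metric_name <- match.arg(metric_name,
                           c("strength", "nodal_efficiency", "clustering"))
  Mn <- normalize_connectome(M)
  n <- M$n
  if (is.null(counts)) counts <- seq(0, n, by = 3)
  if (is.unsorted(counts, strictly = TRUE)) stop("counts must be increasing")
  metric <- node_metrics(M)[[metric_name]]
  rows <- list()
  for (seed in seeds) {
    order_idx <- switch(direction,
      high_to_low = order(-metric, seq_len(n)),
      low_to_high = order(metric, seq_len(n)),
      random = with_seed(seed, sample.int(n)))
    for (k in counts) {
      gm <- make_gain_map(n, alpha, base_r0,
                          targets = head(order_idx, k), target_r0 = target_r0)
      res <- run_condition(Mn, alpha, gm$r0, seed, duration, discard,
                           measures, fc_surrogates, louvain_runs)
      rows[[length(rows) + 1]] <- data.frame(count = k, seed = seed,
                                             R_bar = res$R_bar,
                                             E_w = res$E_w, Q_w = res$Q_w)
    }
  }
  curves <- do.call(rbind, rows)
  auc <- sapply(c("R_bar", "E_w", "Q_w"), function(m)
    vapply(seeds, function(s) {
      sub <- curves[curves$seed == s, ]
      if (all(is.na(sub[[m]]))) NA_real_
      else auc_trapezoid(sub$count, sub[[m]])
    }, numeric(1)))
  auc <- matrix(auc, nrow = length(seeds),
                dimnames = list(paste0("seed_", seeds),
                                c("R_bar", "E_w", "Q_w")))
  structure(list(metric_name = metric_name, direction = direction,
                 counts = counts, base_r0 = base_r0, target_r0 = target_r0,
                 alpha = alpha, curves = curves, auc = auc, seeds = seeds),
            class = "incremental_result")
}

#' Build fixed-size node subsets from meso-scale categories
#'
#' Every subset has exactly `size` nodes. A category smaller than `size` is
#' complemented with random draws from its `pool` (feeders for rich-club and
#' local categories, S2 for S1/S3); a category equal to `size` is used as is;
#' larger categories are an error. `pool_only` categories (feeders, S2) and
#' the `null` category are sampled entirely at random from their pool / all
#' nodes. One subset per realization.
#'
#' @param members integer node indices that must be included (may be empty
#'   for pool-only categories).
#' @param pool integer node indices to complement from.
#' @param size subset size (default 24).
#' @param n_realizations number of random complements (default 10).
#' @param seed integer RNG seed.
#' @return List of integer vectors, one per realization.
#' @export
build_subsets <- function(members, pool, size = 24, n_realizations = 10,
                          seed = 1) {
  members <- as.integer(members)
  if (length(members) > size)
    stop("category larger than the subset size: cannot complement downward")
  need <- size - length(members)
  pool <- setdiff(as.integer(pool), members)
  if (need > length(pool)) stop("complement pool too small")
  with_seed(seed, lapply(seq_len(n_realizations), function(r) {
    extra <- if (need > 0) sample(pool, need) else integer(0)
    sort(c(members, extra))
  }))
}

#' Fixed-size subset neuromodulation across meso-scale categories
#'
#' For each category, builds `n_realizations` subsets of exactly `size`
#' nodes ([build_subsets] rules), sweeps the target r0 over `r0_grid` inside
#' the subset (all other nodes stay at `base_r0`), and reports measures as
#' differences to the matched null subset (random `size`-node draws) of the
#' same realization. AUCs are trapezoids of the delta curves over r0.
#'
#' @param M a [connectome].
#' @param category_sets named list: for each category a list with `members`
#'   (must-include nodes) and `pool` (complement source). A `null` entry is
#'   added automatically (members = none, pool = all nodes).
#' @param seeds realization seeds (one subset draw + one simulation seed per
#'   realization).
#' @param base_r0 baseline slope (default 0.33).
#' @param alpha global coupling (default 0.65).
#' @param r0_grid target slope grid (default seq(0.33, 1, length.out = 5)).
#' @param size subset size (default 24).
#' @param duration,discard simulated time and transient (s).
#' @param measures,fc_surrogates,louvain_runs analysis settings.
#' @return An object of class `subset_result`: `delta_curves` data.frame
#'   (category, r0, seed, dR_bar, dE_w, dQ_w), `auc` (per category x seed,
#'   per measure), `subsets`.
#' @export
subset_neuromod <- function(M, category_sets, seeds = 1:3, base_r0 = 0.33,
                            alpha = 0.65,
                            r0_grid = seq(0.33, 1, length.out = 5),
                            size = 24, duration = 660, discard = 60,
                            measures = c("R_bar", "E_w", "Q_w"),
                            fc_surrogates = 500, louvain_runs = 200) {
  Mn <- normalize_connectome(M)
  n <- M$n
  category_sets$null <- list(members = integer(0), pool = seq_len(n))
  subsets <- lapply(names(category_sets), function(cat) {
    cs <- category_sets[[cat]]
    # subset-draw seed derives from the category content, so two categories
    # with identical definitions draw identical subsets (this makes the
    # null-vs-null delta exactly zero, a sanity property the tests use)
    build_subsets(cs$members, cs$pool, size = size,
                  n_realizations = length(seeds),
                  seed = 7919L + (sum(cs$members) + 131L * sum(cs$pool)) %% 100000L)
  })
  names(subsets) <- names(category_sets)
  measure_run <- function(subset, r0_target, seed) {
    gm <- make_gain_map(n, alpha, base_r0, targets = subset,
                        target_r0 = r0_target)
    run_condition(Mn, alpha, gm$r0, seed, duration, discard,
                  measures, fc_surrogates, louvain_runs)
  }
  # null reference per (realization, r0)
  null_ref <- lapply(seq_along(seeds), function(r)
    lapply(r0_grid, function(r0) measure_run(subsets$null[[r]], r0, seeds[r])))
  rows <- list()
  for (cat in setdiff(names(category_sets), "null")) {
    for (r in seq_along(seeds)) {
      for (ir in seq_along(r0_grid)) {
        res <- measure_run(subsets[[cat]][[r]], r0_grid[ir], seeds[r])
        ref <- null_ref[[r]][[ir]]
        rows[[length(rows) + 1]] <- data.frame(
          category = cat, r0 = r0_grid[ir], seed = seeds[r],
          dR_bar = res$R_bar - ref$R_bar, dE_w = res$E_w - ref$E_w,
          dQ_w = res$Q_w - ref$Q_w)
      }
    }
  }
  delta_curves <- do.call(rbind, rows)
  cats <- unique(delta_curves$category)
  auc <- lapply(c("dR_bar", "dE_w", "dQ_w"), function(m) {
    out <- sapply(cats, function(cat) vapply(seeds, function(s) {
      sub <- delta_curves[delta_curves$category == cat &
                            delta_curves$seed == s, ]
      if (all(is.na(sub[[m]]))) NA_real_ else auc_trapezoid(sub$r0, sub[[m]])
    }, numeric(1)))
    matrix(out, nrow = length(seeds),
           dimnames = list(paste0("seed_", seeds), cats))
  })
  names(auc) <- c("dR_bar", "dE_w", "dQ_w")
  structure(list(delta_curves = delta_curves, auc = auc, subsets = subsets,
                 r0_grid = r0_grid, base_r0 = base_r0, alpha = alpha,
                 size = size, seeds = seeds),
            class = "subset_result")
}
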