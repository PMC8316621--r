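# gainsweep

Whole-brain simulation of noradrenergic-like gain modulation on a weighted
connectome, with the structural and functional network analysis needed to
ask: *which nodes, when their gain is raised, switch the network between
segregated and integrated states?*

The package is aimed at computational neuroscientists studying
neuromodulation with neural mass models. It provides:

* a stochastic **Jansen–Rit network** (8 ODEs per node, Euler–Maruyama at
  1 ms) coupled through a mean-strength-normalized structural matrix, with
  per-node control of the pyramidal sigmoid slope `r0` (filter gain, the
  noradrenergic proxy) and a global coupling `α` (cholinergic-like
  excitability);
* a **generalized hemodynamic model** turning firing rates into BOLD-like
  signals, band-passed 0.01–0.1 Hz with a zero-phase 3rd-order Bessel
  filter and resampled to TR = 2 s;
* **structural analysis**: node strength `K_i^w`, nodal efficiency `E_i^w`
  (inverse-weight shortest paths), Onnela weighted clustering `C_i^w`,
  the normalized weighted rich-club coefficient `φ_norm(K)` against
  degree- and strength-preserving (DSPR) surrogates, and the s-core
  decomposition;
* **functional analysis**: Kuramoto phase synchrony `R̄` of the EEG-like
  signals, Fourier-surrogate-thresholded functional connectivity with
  BH-FDR, global efficiency `E^w`, consensus-Louvain modularity `Q^w`,
  and functional connectivity dynamics (FCD, Clarkson distance between
  sliding-window FC patterns);
* a **synthetic connectome generator** with planted modules and a planted
  rich club, so the whole pipeline is testable without external data;
* the three **experiment protocols**: uniform `(α, r0)` sweeps,
  incremental neuromodulation ranked by a local metric, and fixed-size
  24-node subset neuromodulation per meso-scale category, summarized by
  trapezoidal AUCs and Student's t-tests.

## The model in brief

Per node `i`, the pyramidal potential is
`ν_i = C2·x1_i − C4·x2_i + C·α·Σ_j M̃_ij x3_j` and the firing rate is
`ζ_i = ζ_max / (1 + exp(r0_i (ν_th − ν_i)))`. Raising `r0` in a subset of
nodes is the model's account of selective noradrenergic neuromodulation;
which subsets move the whole network most is the scientific question the
protocols answer (high-strength nodes and rich-club members, as it turns
out — and the package lets you verify both claims on synthetic data).

## Worked example

```r
library(gainsweep)

M <- generate_connectome(seed = 42)   # 90 nodes, 40% density, planted club
M
#> <connectome> 90 nodes, 1602 edges (density 0.400), weights [0, 1]

rc <- rich_club(M, n_surrogates = 200, seed = 1)
rc
#> <rich_club_result> K* = 43, max phi_norm = 1.6315 (p = 0.004975)
#> rich_club    feeder     local
#>        18        71         1

Mn <- normalize_connectome(M)
for (r0 in c(0.33, 0.67)) {
  cfg <- sim_config(duration = 300, discard = 60,
                    gain = gain_map(r0, alpha = 0.65),
                    noise = noise_spec(seed = 1))
  tr  <- simulate_jr(Mn, cfg)                       # EEG-like + firing rates
  bt  <- bandpass_bold(bold_forward(tr), rate = tr$rate)
  fc  <- fc_threshold(bt, seed = 1)
  mod <- modularity_consensus(fc, seed = 1)
  cat(sprintf("r0 = %.2f:  R_bar = %.3f  E_w = %.3f  Q_w = %.3f\n",
              r0, phase_synchrony(tr)$R_bar,
              global_efficiency(fc), mod$Q_w))
}
```

On this synthetic connectome the run prints (the same numbers under the
same seeds on any platform, R's default RNG):

```
r0 = 0.33:  R_bar = 0.207  E_w = 0.545  Q_w = 0.411
r0 = 0.67:  R_bar = 0.819  E_w = 0.906  Q_w = 0.003
```

i.e. raising the filter gain uniformly switches the network from a
segregated state (low synchrony, modular FC) to an integrated one (high
synchrony, efficient near-complete FC, vanishing modularity): `R̄` is the mean Kuramoto order parameter of the alpha-band EEG-like
signals (0 = incoherent, 1 = fully locked), `E^w` the global efficiency of
the thresholded BOLD FC (integration), and `Q^w` its modularity
(segregation). The protocol functions (`incremental_neuromod`,
`subset_neuromod`) repeat such runs while modulating ranked node subsets
and report AUC contrasts. Which ranking wins is a genuine property of the
connectome and the operating point: on this synthetic world,
high-strength-first beats low-strength-first on the rising branch of the
gain–synchrony curve (target `r0 = 0.5`) and the ordering reverses past
the synchronization peak (target `0.67`) — see the vignette's limitations
for the mechanism.

## Command line

A CLI mirroring the main operations is installed with the package:

```sh
CLI=$(Rscript -e 'cat(system.file("cli", "gainsweep", package = "gainsweep"))')
Rscript $CLI synth connectome --n 90 --density 0.4 --seed 1 --out sc.csv
Rscript $CLI connectome richclub --input sc.csv --surrogates 1000 --seed 1 --out results/
Rscript $CLI simulate --sc sc.csv --alpha 0.65 --r0 0.33 --seed 1 --out results/
Rscript $CLI protocol incremental --sc sc.csv --seeds 1,2,3 --out results/
```

## Further reading

The methods vignette (`vignettes/gainsweep-methods.Rmd`) documents the
model equations and parameters, the noise convention, the filter design,
the DSPR null-model algorithm, what the synthetic generator does and does
not emulate, and known limitations.
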