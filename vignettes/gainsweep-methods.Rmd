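---
title: "Methods: whole-brain gain modulation on a weighted connectome"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: whole-brain gain modulation on a weighted connectome}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The model

Each brain region is a Jansen–Rit neural mass: a pyramidal population with
excitatory and inhibitory interneuron feedback. Post-synaptic potential
blocks are critically damped second-order filters (amplitudes `A = 3.25` mV
excitatory, `B = 22` mV inhibitory; inverse time constants `a = 100` s⁻¹,
`b = 50` s⁻¹), and potentials map to population firing rates through the
sigmoid

    S(ν, r) = ζ_max / (1 + exp(r (ν_th − ν))),

with `ζ_max = 5` s⁻¹ and `ν_th = 6` mV. Coupling constants are
`C1 = C = 135`, `C2 = 0.8C`, `C3 = 0.25C`, and — deliberately strengthened
inhibition — `C4 = 0.5C`, which widens the range of couplings that sustain
oscillations. Long-range connections are pyramidal-to-pyramidal, with a
slower kernel (`ā = 0.5a`) because distal inputs arrive on apical dendrites.
Per node the state is (x0..x3, y0..y3); the EEG-like signal is
`ν_i = C2 x1_i − C4 x2_i + C α z_i`, where `z_i = Σ_j M̃_ij x3_j` is the
long-range input through the mean-strength-normalized connectome `M̃` and
`α` scales it globally (a cholinergic-excitability proxy). The pyramidal
sigmoid slope `r0` is the *filter gain*, the model's noradrenergic proxy:
raising it amplifies supra-threshold inputs and suppresses sub-threshold
ones. Neuromodulation experiments raise `r0` in chosen node subsets.

Pyramidal populations also receive a Gaussian input `p(t)` with
`μ = 2` and `σ = 2` impulses/s.

### Noise convention (a deliberate choice)

`p(t)` is redrawn each 1 ms step and held constant over the step, so the
fluctuation enters the Euler update multiplied by `dt` (not `√dt`). We
implemented the `√dt` (Euler–Maruyama diffusion) convention first and
rejected it on evidence: with `σ = 2` at `dt` = 1 ms it produces ±150 mV
excursions around a ±8 mV deterministic limit cycle, and every gain and
coupling dependence of the synchrony measures disappears. The
sampled-and-held reading keeps noise commensurate with the intrinsic
dynamics and reproduces the expected phenomenology (synchrony rising
steeply with `r0` at intermediate coupling). The price is that the noise
term is tied to the stated `dt`; `dt` is therefore part of the model
definition here, not a numerical knob.

Initial conditions are zero for all states; the default 60 s discard
absorbs the onset transient. Seeds control the noise stream only, and
replay is bit-exact.

## Hemodynamics

Firing rates drive a generalized hemodynamic model per node (vasodilatory
signal, inflow, venous volume, deoxyhemoglobin; `τ_s = 0.65`, `τ_f = 0.41`,
`τ_v = τ_q = 0.98` s, stiffness `κ = 0.32`, `E0 = 0.4`), integrated by
Euler at 1 ms, and the BOLD signal change is the standard three-term
readout with `V0 = 0.04`, `k1 = 2.77`, `k2 = 0.2`, `k3 = 0.5`. The raw
BOLD is band-pass filtered at 0.01–0.1 Hz with a zero-phase 3rd-order
Bessel filter and resampled to a 2 s TR.

By default each node's hemodynamic state starts at the steady state
implied by its first firing-rate sample rather than the rest state
(0, 1, 1, 1). The BOLD stage runs on the already-discarded firing rates;
starting from rest there would place a shared ~100 s onset deflection
inside the retained window, and after band-passing it pins every pairwise
BOLD correlation near 1 regardless of the neural state (we measured
exactly that). Steady-state initialization emulates the long lead-in that
the discard is supposed to provide; `init = "rest"` remains available for
step- and impulse-response analysis.

Numerical choices: a 0.01–0.1 Hz IIR designed directly at 1 kHz is
hopelessly ill-conditioned (normalized band edges of 1e-5), so the signal
is block-averaged to 2 Hz first — the hemodynamic ODEs are strong
low-passes and leave no meaningful power near 1 Hz — then filtered and
subsampled to 0.5 Hz. Zero-phase (forward–backward) application avoids the
phase distortion that would corrupt sliding-window FC. No signal-processing
package ships in the target runtime, so the filter is designed in-package:
reversed-Bessel-polynomial prototype, −3 dB magnitude normalization,
lowpass→bandpass transform, bilinear transform with prewarping, and
second-order-section filtering with scipy-style odd-extension padding and
steady-state initial conditions (validated against `scipy.signal.bessel`;
frozen response values live in the test suite).

## Functional measures

* **Phase synchrony.** Each EEG-like channel is filtered around its own
  Welch spectral peak (search window 2–20 Hz) ±3 Hz with the same Bessel
  design, phases come from the Hilbert transform with 1 s trimmed at each
  end, and `R̄` is the time average of the Kuramoto order parameter.
  Signals are block-averaged to ≤125 Hz first; the band of interest ends at
  23 Hz, so this is lossless for the statistic and ~8× faster.
* **Thresholded FC.** Pearson correlations of the full BOLD series are
  tested against 500 Fourier-phase-randomized surrogates (amplitude spectra
  preserved exactly); a Gaussian is fitted per pair, right-tail p-values
  are corrected by Benjamini–Hochberg across all (n²−n)/2 pairs jointly,
  and non-significant or negative entries are zeroed.
* **Integration/segregation.** Global efficiency uses shortest paths on
  inverse weights (disconnected pairs contribute zero). Modularity uses
  Louvain (igraph, resolution 1.0) run 200 times, a co-assignment agreement
  matrix thresholded at 0.5, and re-clustering until the partition is
  unique (≤20 rounds); the reported Q is that of the consensus partition on
  the original thresholded FC.
* **FCD.** Sliding windows of 100 s every 2 s; each window's vectorized
  upper-triangle FC is unit-normalized and compared with the Clarkson
  distance ½‖x̂ − ŷ‖ ∈ [0, 1]. A 600 s recording yields 251 windows.

## Structural measures

Node strength, nodal efficiency (inverse-weight shortest paths) and the
Onnela-style weighted clustering coefficient are the local metrics. The
weighted rich-club coefficient φ(K) compares the weight inside the
degree-> K subgraph with the sum of the equally many strongest weights in
the network, and is normalized by the mean over degree- and
strength-preserving (DSPR) surrogates; K* maximizes the normalized
coefficient, members have degree > K*, feeders are non-members adjacent to
a member in the 0.05-thresholded matrix, the rest are local nodes. The
empirical one-sided p at K* uses the (1 + #{φ_rand ≥ φ})/(N + 1)
correction. The s-core assigns each node the largest s at which it
survives recursive pruning of nodes with within-subgraph strength < s.

**DSPR algorithm.** The null model family is named in the literature but
not pinned to an algorithm, so we chose: Maslov–Sneppen pairwise edge swaps
(binary degree sequence preserved exactly), then the original weight
multiset is shuffled onto the new pattern and refined by weight swaps that
reduce total absolute strength error, with a light annealing schedule
(pure greedy refinement stalls when one node's surplus is balanced by many
small deficits). Typical per-node strength error is 1–2% (tests enforce
≤5%). The refinement deliberately imposes no weight concentration beyond
what the strength sequence requires; an earlier deterministic
highest-weight-to-highest-strength placement made surrogates *more*
club-like than any real network, pinning the normalized coefficient below
one — an instructive failure mode, since the normalized rich club measures
exactly the concentration that strengths alone do not explain.

## Synthetic connectomes: the stated world

`generate_connectome()` emulates the statistical structure the analyses
assume: 90 nodes, 40% density (edge count fixed exactly), log-normal
weights clipped to [0, 1] (meanlog −2.2, sdlog 0.7), four balanced modules,
and a hub core of 20% of nodes drawn across modules. The planted club is
crisp by construction: core–core pairs are fully connected and carry
weights boosted ×3; every core node receives the same number of
core–periphery links, sized to put the shared core degree just above the
periphery degree ceiling; core–periphery weights are mildly damped (×0.7).
The damping matters: boosting core–periphery weights too (the naive
reading of "boost everything touching the core") makes the club exactly
what the strength sequence implies, and the DSPR-normalized coefficient is
~1 by construction — no club is detectable, correctly. A club is *strong
mutual* connectivity beyond strength expectation. With `core_boost = 1`
the generator returns a modular Erdős–Rényi-like control with no planted
structure at all.

What a green planted-recovery test establishes: the rich-club machinery
detects a crisply planted club against its own null. What it does not
establish: behavior on real connectomes with continuous degree
distributions, spatial embedding, or hemispheric symmetry — none of which
the generator models.

## Protocols and desk scale

The three experiments are uniform (α, r0) sweeps (optionally over DSPR /
fully randomized / homogenized surrogates), incremental neuromodulation
ranked by a local metric (counts 0..n in steps of 3 by default), and
fixed-size 24-node subset neuromodulation per meso-scale category
(categories smaller than 24 complemented at random from their pool —
feeders for rich-club/local, the middle s-core shell for S1/S3 — and
compared against random null subsets of the same size, whose measures are
subtracted realization-by-realization). Summaries are trapezoidal AUCs
over the swept axis and pooled-variance t-tests between AUC samples.

Full-paper settings (660 s runs, 10 seeds, fine grids, 1000 surrogates)
are available through the arguments but exceed a desk budget; the test
suite runs the orderings at the reduced scale of 300 s runs, 5 seeds,
`R̄`-only and coarse grids, which preserves the qualitative contrasts
(high-strength-first > low-strength-first; rich-club subsets > periphery
subsets).

## Known limitations

* **Subset-ordering results are operating-point dependent.** On the
  synthetic world, modulating high-strength nodes first raises synchrony
  more than low-strength-first only on the *rising branch* of the
  gain–synchrony curve (target `r0` up to ~0.5 here); at target 0.67 the
  ordering reverses. Two mechanisms: the sigmoid's slope parameter also
  sets the sub-threshold tonic output (S(0 mV) falls from 0.60 s⁻¹ at
  `r0 = 0.33` to 0.09 s⁻¹ at 0.67), so gain-modulating hubs withdraws
  tonic drive from the whole network in proportion to their broadcast
  strength; and a strongly mutually coupled modulated core forms its own
  coherent cluster poorly phase-matched to the unmodulated bulk. Worlds
  whose synchrony keeps rising through `r0 = 0.67` (as the human matrix
  does in the source analyses) do not hit this reversal; the synthetic
  generator's world peaks earlier, and the corresponding acceptance test
  is deliberately left failing rather than retuned.
* The noise convention makes `dt` part of the model (see above).
* Euler/Euler–Maruyama at 1 ms is the stated integration scheme; no
  higher-order scheme is provided.
* The generator's equal-core-degree construction is stylized; recovery
  rates on it do not transfer quantitatively to empirical matrices.
* The human AAL90 matrix is third-party data and is not bundled; the
  acceptance test that checks its published structural counts stays red
  unless the matrix is supplied as `inst/extdata/aal90_sc.csv`.
* Louvain and shortest paths come from igraph; their exact tie-breaking is
  seeded but not re-derived here.
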