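---
title: "Modeling cohesin FRiP and correcting for antibody background"
author: "LoopFRiP authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modeling cohesin FRiP and correcting for antibody background}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(LoopFRiP)
```

## The problem

In mammalian interphase nuclei, cohesin extrudes chromatin loops and is
positioned by CTCF barriers. The fraction of cohesin ChIP-seq reads that
fall in CTCF peaks (FRiP) is a natural quantitative readout of how
effectively CTCF positions cohesin, and comparing it before and after a
perturbation should reveal the roles of cohesin cofactors. Two technical
effects complicate this reading:

1. **Cohesin traffic.** In loop-extrusion models, more cohesins mean more
   cohesin–cohesin collisions, so *fewer* cohesins reach a barrier:
   simulated FRiP *decreases* with cohesin abundance.
2. **Antibody background.** Non-specific antibody capture contributes
   reads roughly uniformly over the genome. Because the total background
   is constant while cohesin-derived reads scale with cohesin abundance,
   the background *fraction* rises under depletion. Enough background
   inverts the abundance–FRiP relationship.

LoopFRiP implements the machinery to quantify both effects and to correct
for the second: a lattice loop-extrusion simulator, an equilibrium
biochemical model of the background, a spike-in based background
estimator, a FRiP denoiser, interval-based FRiP computation, and seeded
generators of synthetic data.

## The loop-extrusion simulator

`simulateExtrusion()` runs a stochastic 1D simulation on a lattice of
`nReplicas * sitesPerReplica` sites. Defaults represent 25 Mb of
chromatin (25 replicas of 1 Mb at 250 bp per site), calibrated on mouse
embryonic stem cells:

| parameter | default | meaning |
|---|---|---|
| `lefSeparationBp` | 250 kb | mean extruder spacing (4 cohesins/Mb); the extruder count is `max(1, round(total/separation))` |
| `lefLifetime` | 1300 s | mean chromatin residence time of an extruder |
| `lefStalledLifetime` | 1300 s | residence time while stalled at a barrier or another extruder |
| `lefBirthRate` | 0.1 | per-step reloading probability of an unloaded extruder |
| `lefPauseRate` | 0 | per-step probability a leg does not move |
| `nSteps` / `stepDuration` | 4000 / 1 s | trajectory length; 1 s steps make lifetimes in seconds commensurate with step counts |
| `burnInFraction` | 0.25 | initial fraction discarded so loop sizes equilibrate |
| `fripWindow` | 1 | half-width (sites) of the barrier window used for FRiP |

Each step applies, in order: (1) barrier state flips with probabilities
`1 - exp(-dt/dwell)`; (2) extruder unloading; (3) reloading at a random
free adjacent site pair (a blocked birth retries next step); (4) outward
translocation of each leg unless paused, blocked by a bound barrier at
the target site (orientation-respecting), blocked by another leg, or at
a lattice end (lattice ends are reflecting). This phase order is a design
choice of this package; the per-step birth probability is interpreted
per step (with 1 s steps, equivalently per second). Extruders are a
conserved pool of loaded plus unloaded units fixed by the separation.
Leg positions recorded after burn-in accumulate into an
`OccupancyProfile`, the in-silico ChIP profile, and `simulatedFrip()`
is the fraction of recorded legs within the union of barrier windows
(window 1 = the barrier site plus both flanking sites).

The kernel is validated in the test suite against an exact
transition-matrix solution of the single-extruder chain on a small
lattice, and by construction checks (boundary accumulation, trapping by
permanently bound barrier pairs, leg-count conservation).

### CTCF barriers

A dynamic barrier is bound (blocking) with mean dwell `bound_time` and
unbound with mean dwell `unbound_time`; its occupancy is
`bound/(bound+unbound)`. Two parameterizations are supported:

* **Homogeneous** (`homogeneousBarrierSet()`): all sites share bound
  time 780 s and unbound time 468 s (occupancy 0.625) — the parameter
  block used for all abundance scans here.
* **Heterogeneous** (`sampleBarrierSet()`): occupancies are drawn with
  replacement from a pool and converted to dwell times through an anchor
  that maps occupancy 0.65 to a 9.87 min bound time. Converting an
  occupancy to dwell times is under-determined; we hold the *unbound*
  time fixed at the anchor's value and scale the bound time, which
  preserves the barrier's rebinding rate while matching the target
  occupancy exactly.

Sampling iterates until the summed occupancy reaches a target of 13
expected bound barriers per Mb (from ~217,200 CTCF copies, ~49% bound,
over an effective 3 × 2.7 Gb genome). Measured occupancy distributions
are not shipped; `defaultOccupancyPool()` is a *synthetic* pool (Beta
quantiles, mean ≈ 0.342) chosen so the sampler draws ≈ 38 sites per Mb,
the density of the baseline heterogeneous simulations. Barrier positions
are uniform without minimum spacing, orientations default to
bidirectional blocking (directional blocking is supported), and one
sampled layout is tiled identically across replicas.

### Abundance scans

`scanCohesinAbundance()` divides the baseline separation by each
abundance ratio (so the ratio multiplies the extruder count) and
`scanCtcfAbundance()` multiplies barrier occupancies. With 20 seeds per
ratio the package reproduces both qualitative behaviors: FRiP falls
monotonically as cohesin abundance rises over ratios 0.1–2 and rises
with CTCF abundance over 0–1 (at ratio 0 FRiP equals the chance level,
the barrier-window coverage of the lattice).

## The biochemical background model

Antibody (A) binds chromatin-bound cohesin (C, dissociation constant
`Kd_s`) and background epitopes (B, `Kd_n`). With the reference reagent
quantities (25 µg DNA, 5 µg IgG at 150,000 g/mol, 500 µL), total
antibody is 6.67 × 10⁻⁸ M while loaded cohesin (4/Mb, converted through
the scale constant σ = Mb-count / N_A / volume) is ~0.25% of it, so free
antibody ≈ total antibody. Then the antibody-bound background
`[AB] = [A] B_total / (Kd_n + [A])` is independent of cohesin abundance:
total background reads θ are a *constant*. `equilibriumExact()` solves
the full mass-action system by 1D root finding and confirms the
approximation to within 0.5% in this regime.

Writing the background fraction `f = θ / ([AC] + θ)` and scaling cohesin
reads by a relative abundance γ gives the rescaled fraction

    f(γ) = f_base / (γ (1 − f_base) + f_base),

implemented in `backgroundFractionAtAbundance()`. The observed FRiP of a
mixture with background fraction `f` is
`(1 − f) · FRiP_true + f · ρ`, with ρ the genome fraction in peaks
(`peakGenomeFraction()`; the in-silico analogue is
`barrierWindowCoverage()`). `backgroundAdjustedScan()` applies both to a
simulated scan, and `monotonicInversionThreshold()` finds the smallest
baseline fraction on a 0.05-step grid at which the adjusted curve
becomes nondecreasing in γ — about 0.35 under the baseline conditions.
A grid is used rather than bisection because the underlying scan is
stochastic; with 20–100 seeds per ratio the estimate is stable to about
one grid step. Under the alternative proximal-crosslinking background
(background scales *with* cohesin), `f` is γ-invariant and the adjusted
curve keeps the raw decreasing trend at any background level, so only an
abundance-independent background source can invert the trend.

One bookkeeping note: θ and `[AC]` are carried in "calibrated read"
units proportional to concentration × volume; the proportionality
constant cancels in every fraction and is fixed at 1. The wash-noise
term ε defaults to 0 and is absorbed into θ.

## Spike-in background estimation and denoising

With spike-in calibrated reads before (`R_UT`) and after (`R_dep`)
depleting the target to a remaining relative abundance γ (measured
externally — the package never infers it),

    f_UT = (R_dep / R_UT − γ) / (1 − γ)          (estimateFUT)

recovers the unperturbed background fraction exactly on noiseless pairs,
while the naive ratio `R_dep / R_UT` strictly overestimates it whenever
γ > 0 and f < 1. The depleted sample's fraction follows from the same
rescaling (`fDepFromFUT()`). Denoising removes background from both
parts of FRiP:

    denoised = (FRiP − f ρ) / (1 − f)            (denoiseFrip)

and is the exact inverse of the forward mixture. Out-of-range denoised
values are returned with a warning rather than clipped: they diagnose a
mis-specified `f` or ρ.

## Synthetic data

The generators in this package are first-class, seeded and
bit-reproducible:

* `genGenome()`, `genPeaks()` — fixed-width non-overlapping peaks with
  exact ρ (e.g. 80 × 300 bp on 3 Mb gives ρ = 0.008, the ~0.8% scale of
  CTCF peaks on a mammalian genome).
* `genReads()` — the generative twin of the mixture model: background
  reads uniform over the genome, signal reads in a random peak with
  probability `q`; expected FRiP is `(1 − f) q + f ρ` up to edge effects
  below `readLength / chromLength`.
* `genSpikeinPair()` — pairs obeying `R_dep = R_UT (f + γ (1 − f))`,
  optionally Poisson-sampled.
* `profileToReads()` — converts a simulated profile to reads on a toy
  genome (each read confined to its source lattice site), bridging the
  simulator to interval FRiP.

These emulate uniform background and fixed fragment lengths only; they
deliberately omit GC bias, mappability, fragment-length variation and
hotspot-structured background, so green tests certify the algebra and
the simulator, not robustness to those real-data features.

## Numerical and design choices

* Intervals are 0-based half-open on disk (BED) and 1-based closed in
  memory (`GRanges`); flattening merges book-ended intervals
  (coverage-union semantics), and a read counts toward FRiP when it
  shares ≥ 1 bp with the flattened peak set — matched exactly by a
  brute-force oracle in the tests.
* Occupancies are capped at `1 − 1e-6` when scaling so dwell times stay
  finite; occupancy → time conversion rejects occupancy 1, while sampled
  pools may contain 1 (permanent barriers, infinite bound time).
* All randomness flows from explicit integer seeds; scans derive one
  child seed per (ratio, seed) pair with a Lehmer step kept below 2^31.
* Problem sizes in the test-suite scans (20 seeds per ratio on the full
  25 Mb lattice; 100 seeds in the acceptance script) were chosen as the
  smallest giving a grid-stable inversion threshold.
* Where the cohesin-abundance scan is degenerate (flat), the inversion
  threshold is the smallest grid value, since any positive uniform
  background then makes the adjusted curve increase through `f(γ)`
  alone.

## Limitations

The simulator is 1D: it does not model 3D polymer contacts, Hi-C maps,
or cofactor-specific extrusion rules, and replicas share one barrier
layout. The biochemical model assumes equilibrium binding, antibody
excess, background weaker than signal, and uniform background targets.
The background estimator additionally assumes equal accessible-epitope
abundance across samples before depletion; differences in recovery
between experiments violate this and bias the estimate.
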