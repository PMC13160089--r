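# LoopFRiP

Loop-extrusion simulation and background correction for ChIP-seq FRiP.

## What this package is for

Cohesin extrudes chromatin loops and is positioned by CTCF barriers; the
fraction of cohesin ChIP-seq reads in CTCF peaks (**FRiP**) quantifies how
effectively CTCF positions cohesin. Interpreting FRiP changes after
perturbations is confounded by two opposing effects that this package
models quantitatively:

* **Extrusion traffic.** In a 1D loop-extrusion model with dynamic CTCF
  barriers, more cohesins collide more often, so simulated FRiP
  *decreases* as cohesin abundance rises and *increases* with CTCF
  occupancy.
* **Antibody background.** An equilibrium binding model of antibody,
  cohesin and background epitopes shows that, with antibody in excess,
  total background reads θ are constant in cohesin abundance, so the
  background fraction rescales under a relative abundance γ as

      f(γ) = f_base / (γ·(1 − f_base) + f_base)

  and the observed FRiP of a mixture is `(1 − f)·FRiP_true + f·ρ`, with
  ρ the genome fraction in peaks. Enough uniform background (baseline
  fraction ≈ 0.35 under the baseline simulation conditions) *inverts*
  the FRiP–abundance trend.

The package also implements the resulting correction strategy: with
spike-in calibrated reads before (`R_UT`) and after (`R_dep`) depleting
the target to a remaining fraction γ,

    f_UT = (R_dep/R_UT − γ) / (1 − γ)        (background estimate)
    denoised FRiP = (FRiP − f·ρ) / (1 − f)   (denoising)

plus interval-based FRiP/ρ computation on BED/narrowPeak data and seeded
synthetic-data generators, so everything is testable offline.

## Worked example

```r
library(LoopFRiP)

# CTCF barriers: bound 780 s / unbound 468 s (occupancy 0.625),
# sampled to 13 expected bound barriers per Mb
barriers <- homogeneousBarrierSet(seed = 1)

# baseline conditions: 25 Mb lattice, 100 extruders, 4000 steps
params <- SimParams(seed = 1L)
prof <- simulateExtrusion(params, barriers)
simulatedFrip(prof, barriers)
#> [1] 0.5855952

# cohesin-abundance scan (here 5 seeds per ratio for speed)
scan <- scanCohesinAbundance(c(0.1, 0.25, 0.5, 1, 1.5, 2),
                             params, barriers, seeds = 1:5)
scan[, 1:2]
#>   ratio frip_mean
#> 1  0.10 0.5958216
#> 2  0.25 0.6041361
#> 3  0.50 0.5724646
#> 4  1.00 0.5352321
#> 5  1.50 0.5178608
#> 6  2.00 0.4796321

# smallest baseline background fraction that inverts the trend
rho <- barrierWindowCoverage(barriers, window = 1)
monotonicInversionThreshold(scan, rho)
#> [1] 0.4

# spike-in background estimation and denoising
pair <- SpikeInPair(rUT = 100, rDep = 30, gamma = 0.1)
estimateFUT(pair)            # 0.222: naive ratio 0.30 would overestimate
#> [1] 0.2222222
denoiseFrip(0.3032, f = 0.4, rho = 0.008)
#> [1] 0.5
```

The scan shows mean simulated FRiP per abundance ratio: FRiP falls from
~0.60 at one-tenth of baseline cohesin to ~0.48 at twice baseline. The
threshold is the smallest baseline background fraction (0.05-step grid)
at which the background-adjusted curve increases monotonically instead;
with only 5 seeds per ratio it lands at 0.4 here, and stabilizes near
0.35 with 20 or more seeds per ratio.

A config-driven runner covers the same operations from the shell
(`runCommand()`; thin wrapper script in `inst/scripts/loopfrip`).

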