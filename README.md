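# sobolclimb

Simulation toolkit for **high-throughput, low-iteration optimization of
multi-gene expression systems**. In metabolic engineering the expression
level of each pathway gene is a continuous design variable and the
measured output (product titer, biosensor signal) is the fitness; modern
DNA assembly makes it cheap to build *hundreds of designs per
design-build-test cycle* but expensive to run *more cycles*. How
aggressively such a campaign can search depends on the **ruggedness** of
the expression landscape — how many local optima separate the start from
the global maximum.

`sobolclimb` implements both halves of the workflow:

1. **Ruggedness quantification.** Landscapes are sums of axis-aligned
   Gaussian sub-peaks over a bounded expression space,
   `f(p) = Σᵢ Aᵢ exp(−Σ_d (p_d − c_{id})² / (2 s_{id}²))`. The landscape
   is sampled on a 200 × 200 grid; all pairwise squared fitness
   differences are binned by Euclidean distance (100-unit bins to 700)
   and normalized by the 600–700 bin to form the landscape
   autocorrelation `LA(x) = 1 − σ²_{d=bin(x)} / σ²_landscape`, which is
   then fitted by least squares with the NK-model reference curve
   `f(x) = (1 − x/N)(1 − k/N)ˣ`, N = 700. The fitted **k** is the
   ruggedness summary: k = 0 is a smooth additive landscape, larger k
   means more, deeper local optima.
2. **Batch optimizers.** Three algorithms that sample `n` designs per
   iteration from a seeded, scrambled **Sobol sequence** shaped into a
   normal cloud of radius σ around the current center, keep the top
   fraction **F** as parents, and recenter: plain **hill climbing**
   (parent mean), **projection** (twice the vector to the parent mean —
   faster uphill, can overshoot), and a simplified **CMA variant**
   (fitness-weighted mean plus an adaptive sampling-shape matrix). Runs
   are scored by *performance* (area under the 5-iteration center-fitness
   curve) and *reliability* (standard deviation over 5 replicate runs),
   and `parameter_sweep()` maps both over a (σ, F) lattice.

Built-in model landscapes `smooth` / `medium` / `rugged` share identical
sub-peak centers and heights and differ only in spread, calibrated so
the default protocol fits k ≈ 0.832, 1.07 and 2.07.

## Worked example

```r
library(sobolclimb)
trio <- builtin_model_landscapes()

# How rugged is the medium landscape? (100 x 100 grid for speed)
quantify_ruggedness(trio$medium, points_per_axis = 100)
#> <ruggedness_fit: k = 1.0415 (N = 700, RSS = 0.0881, converged)>

# Optimize the smooth landscape: 5 iterations x 50 designs, keep top 20%
cfg <- optimizer_config("hill_climb", start = c(300, 700),
                        sobol_radius = 200, samples_per_iteration = 50,
                        iterations = 5, parent_fraction = 0.2, seed = 42)
run_optimization(cfg, trio$smooth)
#> <optimization_trace: hill_climb, 5 iterations, performance 180.6>
#>   center fitness by iteration: 32.03 36.75 37.29 37.28 37.3
```

The fitted `k = 1.04` places the medium landscape between a smooth
additive system (k = 0) and a moderately rugged one. The trace shows the
center fitness climbing from 32.0 at the start coordinates to 37.3 — the
landscape's global maximum region — within three iterations; the
performance score 180.6 is the sum of the five center fitnesses, so it
rewards reaching high fitness *early*.

A command-line wrapper with `ruggedness`, `optimize`, `sweep` and
`landscape` subcommands is installed at
`system.file("scripts", "sobolclimb", package = "sobolclimb")`.

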