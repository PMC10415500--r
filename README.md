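# turingfit

Predicting reaction–diffusion parameters from a **single** observed Turing
pattern.

Diffusion-driven (Turing) instabilities underlie many developmental
patterning processes — digit formation, hair-follicle spacing, animal coat
markings — but fitting a reaction–diffusion model to an observed pattern is
hard: the arrangement of spots or stripes depends sensitively on initial
conditions that are unknown in practice, so two patterns from identical
kinetics can look completely different.  `turingfit` implements a learning
approach for this inverse problem, using the two-species Gierer–Meinhardt
model

```
f(u) = ( a − b·u₁ + u₁²/(u₂(1 + c·u₁²)),  u₁² − u₂ ),    D = s·diag(1, δ)
```

as the working example.  The pipeline:

1. **Simulate** steady-state patterns on a doubly periodic grid with an
   implicit-Euler scheme whose linear solves are FFT symbol divisions
   (compiled core for the Gierer–Meinhardt kinetics, reference R path for
   arbitrary kinetics), including linear stability analysis — dispersion
   relations and the three-condition Turing instability test.
2. **Represent** each pattern by a *resistance distance histogram* (RDH):
   edges of the grid graph are weighted 1 inside high/low regions and
   ε = 0.003 across the field mean; effective electrical resistances between
   nodes within a radius are pooled into a normalised 12-bin histogram.
   RDHs are invariant under shifts and rotations and stable against
   initial-condition noise — which is what makes single-pattern inference
   possible.  Two scalar features (maximal plateau concentration `c_m`,
   high-region component count `n_c`) break the remaining symmetries.
3. **Learn** the histogram → parameter map with ε-insensitive SVR under a
   Wasserstein histogram kernel (1-D optimal transport with squared
   bin-index cost, evaluated by the exact quantile closed form), with
   operator-valued-kernel joint regression of all four parameters (Kronecker
   system solved matrix-free by global GMRES, Gaussian-mixture pre-image by
   line-search descent), or with small ReLU feedforward networks trained by
   Adam with early stopping.
4. **Evaluate** with the normalised RMSE under a 60/20/20
   train/validation/test protocol with disjoint-subset averaging for small
   datasets, and **cluster** pattern collections through a Wasserstein
   neighborhood graph.

## Worked example

```r
library(turingfit)

model <- gm_model(a = 0.01, b = 1.2, c = 0.7, delta = 40, s = 1)
is_turing_unstable(model)$conditions
#> stable_without_diffusion     unstable_at_finite_q        damped_at_large_q
#>                     TRUE                     TRUE                     TRUE

pat <- simulate_pattern(model, grid_spec(64), sim_config(), seed = 1)
round(pat$amplitude, 2)
#> [1] 1.21

vals  <- pattern_features(pat, r = 8)          # resistance value multiset
R_max <- calibrate_rmax(list(vals))            # 99%-quantile histogram edge
h     <- rdh_from_values(vals, r = 8, B = 12, R_max = R_max)
round(h$hist, 3)
#>  [1] 0.000 0.095 0.261 0.189 0.025 0.002 0.000 0.000 0.080 0.175 0.126 0.047
```

The histogram is the pattern's invariant fingerprint: its mass at low
resistances reflects compact well-connected regions, the tail reflects
long-range structure.  Training a predictor end to end (here: 20 patterns,
scalar target `c`):

```r
sweep <- sweep_spec(a = 0.02, b = 1, c = c(0, 1.15), delta = 100, s = 0.25,
                    n_requested = 20, n_r = 32, base_seed = 31)
rep <- run_experiment(sweep, targets = "c", method = "svr", m = 20, r = 8)
c(svr = rep$mean_nrmse, mean_baseline = rep$baseline_nrmse)
#>           svr mean_baseline
#>     0.2017742     1.3305009
```

so even 12 training patterns at this reduced grid size cut the trivial
mean predictor's error by a factor of six; with the full protocol (64×64 grids, pools of
100+) the SVR reaches test NRMSE ≈ 0.2 at 20 training points, the
published small-sample operating point.

A thin CLI covers the shell-friendly steps
(`exec/turingfit {dispersion, check-turing, simulate, featurize, cluster}`);
training and evaluation are R-level functions.

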