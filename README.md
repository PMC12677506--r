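# multiexpT1

Can several longitudinal relaxation times be estimated from a single voxel's
inversion-recovery (IR) signal accurately enough to delineate cortical
layers in the relaxation domain at 3 T? This package provides the machinery
to study that question quantitatively: a synthetic composite phantom suite
with known per-voxel T1 composition, three canonical multiexponential
estimators, and an evaluation layer that scores estimates against ground
truth across the degrees of freedom that matter — the T1 ratio of the
components, their number, and a method's ability to identify that number.

The signal model is the discrete multiexponential IR curve

    y(TI_i) = sum_j A_j (1 - 2 exp(-TI_i / T1_j)),

observed either as a complex signal (before magnitude reconstruction) or as
|y| on 50 inversion times spanning 100–5000 ms. The estimators are:

- **ILT** — inverse Laplace transform: nonnegative least squares of the
  polarity-restored signal over a 100-point candidate T1 grid, followed by
  thresholded (0.075) extraction of contiguous spectral runs as components.
  The NNLS is an in-package Lawson–Hanson active-set solver (`nnlsSolve()`)
  that is rank-tolerant, so it handles the underdetermined 50 × 100 kernel.
- **MUL** — bounded nonlinear least squares of the absolute-value model
  fitted directly on magnitude data with 32 random starts; fixed number of
  components; lowest-SSE solution wins.
- **TOM** — same objective, a single semi-random start per model order
  (T1 starts sample 700–2200 ms), model orders J = 2…jmax fitted
  sequentially and selected by SSE.

Evaluation aligns estimated to true components by exhaustive permutation
search minimizing total T1 relative error, supports zero-component
augmentation (an artificial amplitude-0 truth component) with a modified
maximum mean error for amplitudes, and summarizes errors by method,
component count, and dataset T1 ratio, including an ordinary least-squares
regression of error on ratio.

## Worked example

```r
library(multiexpT1)

# The ten composite datasets at their nominal conditions (SNR 30 dB,
# 36 voxels each); zero dispersion reproduces the design ratios exactly.
suite <- buildCompositeSuite(suiteConfig(dispersion = 0), seed = 1)
round(vapply(suite, meanT1Ratio, numeric(1)), 2)
#>  Comb-1  Comb-2  Comb-3  Comb-4  Comb-5  Comb-6  Comb-7  Comb-8  Comb-9 Comb-10
#>    1.62    2.40    4.26    1.48    2.63    1.77    1.55    2.13    1.63    1.63

# Fit the widest-ratio dataset (641 vs 2733 ms) with all three methods
suite <- buildCompositeSuite(suiteConfig(), seed = 1)
d <- suite[["Comb-3"]]
recs <- rbind(
  evaluateDataset(d, fitDataset(d, "ilt", seed = 1)),
  evaluateDataset(d, fitDataset(d, "mul", seed = 1)),
  evaluateDataset(d, fitDataset(d, "tom", seed = 1)))
aggregate(cbind(meanRelErrT1Pct, nEstComponents) ~ method, recs, mean)
#>   method meanRelErrT1Pct nEstComponents
#> 1    ilt       41.825413       2.833333
#> 2    mul        7.241227       2.000000
#> 3    tom        7.241242       2.000000
```

At a T1 ratio of 4.26 the nonlinear fitters recover the two relaxation
times to within about 7% on average, while the spectrum method — which must
place weight on a fixed grid and frequently splits an off-grid component
across non-adjacent bins — sits near 40% and often reports three spectral
runs. Re-running the same code on `Comb-4` (ratio 1.48) raises the
multistart error to about 47%: the error is governed by the ratio of the
relaxation times, which is the central feasibility obstacle for
relaxation-domain laminar imaging.

A full simulation → fit → evaluation → report run, with CSV tables and a
YAML run log:

```r
res <- runPipeline(pipelineConfig(outDir = "run1", seed = 1))
res$summaries$errorsByComponents
```

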