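# spatrisk

Risk estimation for fixed predictive models under spatial covariate shift.

## The problem

A model `f̂` is trained and validated on labeled data from a **source**
distribution `g(x)` — say, species records from well-surveyed regions, or
cells from one tissue section — and then deployed on an unlabeled **target**
distribution `p(x)` with a different spatial structure. The quantity of
interest is the target risk

    R(e, p) = ∫ e(x) p(x) dx,      e(x) = e(f(x), f̂(x)),

the expected error of the *fixed* model under the target distribution, which
cannot be computed directly because target labels are unavailable. Naive
hold-out estimates on source data are biased as soon as `p ≠ g`, and spatial
data make the shift severe: survey effort clusters, environmental gradients
move, sampled supports stop overlapping.

`spatrisk` implements and benchmarks four reweighting estimators of
`R(e, p)` that use only labeled source samples and unlabeled target samples:

| method | weight on source error `e(x_i)` |
|---|---|
| **NW** (no weighting) | `1` — the biased baseline |
| **IW** (importance weighting) | `p̂(x_i)/ĝ(x_i)` from multivariate Gaussian KDEs with Scott's-rule bandwidth matrices `H = Σ̂ n^(−2/(d+4))` |
| **Classifier** | `(n_g/n_p)(1/P̂(g|x_i) − 1)` from a gradient-boosted source-vs-target classifier, clipped |
| **KMM** (kernel mean matching) | the solution of `min_w ‖(1/n_p)Σφ(x'_j) − (1/n_g)Σ w_iφ(x_i)‖²` s.t. `0 ≤ w ≤ B`, `Σw = n_g` |

KMM matches the weighted source sample to the target sample in the RKHS of an
RBF kernel (bandwidth `σ² = median‖x_i−x_j‖²/log n`), so it never estimates a
density — the step where IW fails in higher dimensions. Each estimate is then
`R̂ = (1/n) Σ w_i e(x_i)` on the source test partition, benchmarked against
the ground-truth mean error on the labeled target test partition via MAPE,
RMSE and RMSPE.

The package also provides a **local correlation function (LCF)** diagnostic —
a bounded, scale-invariant curve over radius comparing each point's neighbor
count with a matched uniform (CSR) reference — whose area summarizes spatial
clustering and decides which member of a dataset pair is the clustered source;
a fully seeded simulator of ten bidirectional shift scenarios on `[0,100]^d`
(domain truncation, mode expansion/contraction, correlation shift/restoration,
variance scaling, support mismatch); and a risk-guided model-selection
experiment over a pool of boosted and random-forest classifiers.

## A worked example

```r
library(spatrisk)

cfg  <- scenario_config("support_mismatch_gmm_to_uniform",
                        d = 2, n_points = 2000, seed = 5)
trial <- run_trial(cfg, seed = 5)
sapply(trial$estimates, function(x) x$value)
#>          gt          nw          iw  classifier         kmm
#> 0.012664471 0.005407470 0.006033796 0.007036551 0.010505000
```

A gradient-boosted regressor is fitted on the clustered source's training
half and its squared error is averaged under each weighting. The ground truth
(`gt`, computable here because the simulator labels the target) is 0.0127;
no-weighting underestimates it by 57%, the KDE density ratio by 52%, while
KMM comes within 17%. Repeating over seeds and scenarios:

```r
tab <- run_experiment(cfg, n_reps = 20, master_seed = 42)
subset(as.data.frame(tab), metric == "mape")
#>  nw 67.1   iw 67.0   classifier 51.0   kmm 37.0   (percent, 20 repetitions)
```

The same pipeline runs from the shell:

```sh
Rscript exec/spatrisk simulate --scenario mode_contraction --n 2000 --out runs/sim
Rscript exec/spatrisk estimate --scenario mode_contraction --n 2000 --reps 20 --out runs/est
Rscript exec/spatrisk lcf      --scenario mode_contraction --n 2000 --out runs/lcf
```

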