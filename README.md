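# cperceiver

Continuous patient-state attention models for irregular clinical time series,
in pure R.

## The problem

ICU data arrive as irregular multivariate time series: vitals and labs are
recorded when care requires, so an hourly grid over the first 48 hours of a
stay has many completely missing time steps. `cperceiver` implements and
studies a family of models for predicting in-hospital mortality from such
series:

- **Perceiver** — a cross-attention encoder in which a bank of $l \le T$
  learnable latents $Z \in \mathbb{R}^{l\times e}$ queries the sequence
  ($Q = Z$, $K = V = X$) through scaled dot-product attention
  $\alpha(Q,K,V) = \mathrm{softmax}(QK^\top/\sqrt{d_k})V$, squeezing $T$
  time steps into $l$ latents at cost $O(Tl)$ instead of the transformer's
  $O(T^2)$, followed by self-attention on the latents;
- **transformer** — the identical pipeline with self-attention throughout;
- **COPER / CTransformer** — continuous variants in which a neural ODE
  $dZ/dt = f_\theta(Z(t), t)$ learns the patient-state dynamics from the
  embedded irregular observations, so a regular series can be resampled at
  any times and fed to the encoder (handling completely missing steps
  without imputation);
- **LSTM and attention baselines on carry-forward imputation** (a missing
  step repeats the most recent observation).

Around the models the package provides a synthetic ICU-like cohort generator
with controllable class separation and missingness, an irregularity
experiment harness (0/25/50/75% of time steps removed), exact analytic FLOP
accounting for both encoders, MC-dropout predictive uncertainty with
clinician-referral curves, and a CLI. All neural components — attention
blocks, layer norm, the embedding MLP, a 2-layer LSTM, and a differentiable
fixed-step RK4 ODE solver — are implemented natively with hand-derived
reverse-mode gradients (no deep-learning framework is required).

## Worked example

Generate a 400-patient synthetic cohort (48 hourly steps, 8 features, 30%
prevalence, observation noise 0.25), train COPER, and evaluate:

```r
library(cperceiver)

cohort <- generateCohort(cohortSpec(n = 400, T = 48, D = 8,
                                    noiseSd = 0.25, seed = 1))
cohort <- splitCohort(cohort, seed = 1)
cohort
#> PatientCohort: 400 patients, 8 features, prevalence 0.300
#> split
#> test train   val
#>    80   256    64

model <- buildModel(modelConfig(kind = "coper", seed = 1), T = 48, D = 8)
model
#> cpsModel kind='coper' (T=48, D=8, e=32): 94209 parameters, untrained

model <- trainModel(model, cohort, trainConfig(maxEpochs = 12, seed = 1))
round(unlist(evaluateModel(model, cohort, "test")), 3)
#>      auroc      auprc   accuracy          n prevalence
#>      0.843      0.722      0.812     80.000      0.275
```

AUROC/AUPRC are the test-set ranking metrics; at this problem size COPER
separates the classes well within a dozen epochs (the larger n = 800 runs
in the acceptance checks reach AUROC ≈ 0.9). The FLOP comparison between
the two encoders (key width 128, latent width 64, `M = N = 1`):

```r
sw <- latentSweep(48L, attentionConfig(e = 32L, dk = 128L, latentDim = 64L))
sw[sw$l %in% c(1, 12, 24, 48), ]
#>     l perceiver transformer     ratio
#> 1   1   1046455     7190082 6.8708946
#> 12 12   3956626     7190082 1.8172256
#> 24 24   7274050     7190082 0.9884565
#> 48 48  14355586     7190082 0.5008560
```

With one latent the Perceiver needs ~6.9× fewer floating-point operations
than the transformer; the totals cross over near $l = 24$, so the squeeze
only pays while $l$ is well below $T$. Uncertainty-aware referral:

```r
ps <- mcDropoutPredict(model, cohort, split = "test", S = 25, seed = 1)
selectivePredictionCurve(ps, fractions = c(0, 0.1, 0.2))
#>   fraction nReferred nRetained  accuracy
#> 1      0.0         0        80 0.8250000
#> 2      0.1         8        72 0.8194444
#> 3      0.2        16        64 0.8437500
```

Referring the most uncertain fifth of test cases to a clinician raises
accuracy on the retained cases from 0.825 to 0.844.

A shell interface with `simulate | train | evaluate | experiment | refer |
flops` subcommands lives at `inst/cli/cperceiver.R`; every output directory
receives a `manifest.json` sufficient to re-run the command bit-identically.

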