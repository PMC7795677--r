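# emofuse

Fine-grained valence–arousal recognition from wearable physiological
signals.

## The problem

When a person watches short videos, their emotional state — described by
the two dimensions of Russell's circumplex model, **valence**
(pleasantness) and **arousal** (activation), annotated continuously on a
1–9 scale — changes on the order of seconds. `emofuse` classifies the
valence and arousal of every short *instance* (default 2 s) of a
multi-channel physiological recording made with wearable sensors
(electrodermal activity, blood volume pulse, skin temperature, heart
rate, pupil/saccade metrics), rather than assigning one label per video.

A 2 s window of wearable signals rarely contains enough information on
its own, so the pipeline combines:

1. **Intra-modality feature learning** — a shallow two-layer
   convolutional autoencoder per modality (a 1×C channel-fusion
   convolution, then a temporal convolution with kernel `c = L/4` whose
   two filter maps flatten to a code of dimension `ω = 2L`), trained by
   binary cross-entropy with adadelta and early stopping.
2. **Correlation-based feature extraction** — for each video stimulus
   *t*, a regularized canonical correlation analysis between the two
   modalities' codes: with `S_jj = φ_j'φ_j/(m−1) + I` and
   `C_12 = φ_1'φ_2/(m−1)`, the SVD of `S_11^{-1/2} C_12 S_22^{-1/2}`
   gives projections `H1 = S_11^{-1/2}U_K`, `H2 = S_22^{-1/2}V_K`, and
   fused features `F_t = [φ_1t H1, φ_2t H2] ∈ R^{m×2K}` (`K = L/2`).
   Instances under the same stimulus are fused because the same video
   evokes similar affect trajectories across subjects.
3. **Broad learning system classification** — random feature nodes
   refined by a sparse (lasso/ADMM) autoencoder, `tansig` enhancement
   nodes with shrinkage `S = 1200`, and output weights solved in closed
   form by ridge pseudo-inverse `W = (E'E + 2^{-30} I)^{-1} E' y`; no
   gradient descent.

Evaluation protocols (leave-one-subject-out and subject-dependent
10-fold CV, both leakage-free by construction), an ablation harness,
instance-length and sampling-rate sweeps, and a synthetic multi-rate
dataset generator with a planted stimulus-locked affect process are
included. See the methods vignette
(`vignettes/emofuse-methods.Rmd`) for the model details and design
choices.

## Worked example

Generate a small synthetic dataset (5 subjects × 3 stimuli × 48 s
trials; two modalities sampled at 64/4/4/1 Hz and 3 × 10 Hz, 20 Hz
continuous annotation), preprocess it into 2 s instances at 32 Hz, and
evaluate the full pipeline subject-independently:

```r
library(emofuse)

cfg    <- synth_config(n_subjects = 5, n_stimuli = 3, trial_seconds = 48, seed = 7)
ds     <- generate_dataset(cfg)
inst   <- preprocess_dataset(ds)
inst
#> emofuse instance set: 360 instances, L = 64 (2 s @ 32 Hz), C1 = 4, C2 = 3

report <- run_losocv(inst, pipeline_config(seed = 7))
report
#> emofuse losocv report (binary, ifl_cfe_bls)
#>   valence  accuracy 0.7917  weighted F1 0.8005  (5 folds)
#>   arousal  accuracy 0.8778  weighted F1 0.8821  (5 folds)

report$tasks$valence$confusion
#>       pred
#> truth  low high
#>   low   47   28
#>   high  47  238
```

Each of the 360 instances is one 2 s window; the report averages
accuracy and weighted F1 over the five held-out subjects. For each held
subject, every stage — autoencoders, per-stimulus CCA, z-scoring, BLS —
is refit on the other four subjects only. Accuracy rises with dataset
size: at the generator's default scale (20 subjects × 8 stimuli × 120 s,
SNR 5) the same protocol reaches ≈ 0.92 binary accuracy for both
dimensions. Class imbalance is intentional: continuous annotation is
neutral-heavy, and neutral discretizes to High on the binary scale,
which is why weighted F1 accompanies accuracy throughout.

Other entry points: `run_sd_10fold()` (subject-dependent),
`run_ablation()` (classifier-only / codes-only / fusion-only / full),
`sweep_instance_length()`, `sweep_sampling_rate()`, and
`read_dataset()`/`write_dataset()` for the long-CSV + YAML-manifest
layout. A thin command-line wrapper with the same operations is
installed at `inst/scripts/emofuse`.

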