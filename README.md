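# hybridseek

Seizure prediction from multi-channel scalp EEG. The package classifies
short EEG analysis windows as **preictal** (inside a configurable horizon
before a seizure onset, by default the lower end of the conventional
60–90 min range) versus **interictal** (seizure-free baseline), the core
decision behind early-warning systems for people with epilepsy. It is aimed
at researchers in biomedical signal processing who want a complete,
reproducible, dependency-light pipeline they can run on their own EDF
recordings or on the package's seeded synthetic records.

## What is inside

* **I/O and preprocessing** — EDF (European Data Format) reading/writing
  with a sidecar seizure-annotation CSV (`source_id,onset_s,offset_s`),
  anti-aliased downsampling, a zero-phase 4th-order Butterworth 0–75 Hz
  band-pass, and non-overlapping window cutting with ictal exclusion and a
  postictal guard.
* **Features** — each window is split into the five classical bands, delta
  (0–4 Hz), theta (4–8), alpha (8–13), beta (13–22), gamma (22–30), and
  summarized per band and channel by eight features

  F = {F_MN, F_VR, F_SDN, F_SKW, F_KRT, F_WEY, F_WEN, F_HEN}:

  mean, variance, standard deviation, skewness Σ(A_r−Ā)³/(q·d³), kurtosis
  Σ(A_r−Ā)⁴/(q·d⁴), relative wavelet (db4, level 5) detail energy
  B(w)/Σ B, wavelet entropy −Σ p_w log₂ p_w over the relative sub-band
  energies, and a 16-bin amplitude histogram entropy.
* **Hybrid seek optimizer** — a crow-search move (follow a random
  flock-mate's memorized best, J_e + λ₁·a·(Z_f − J_e), with an awareness
  probability triggering uniform relocation) and a sparrow-search move
  (best agent: J_e + χ·|J_e − J_worst|/((j_e − j_ws) + ς); others:
  J_best + θ·|J_e − J_best(1 + ν₁ϖ) + V|) averaged into one proposal,
  J = 0.5·J_CS + 0.5·J_GS, with reject-infeasible bounds and strict memory
  elitism. It drives wrapper feature selection (mask = coordinates ≥ 0.5)
  and tunes the ensemble fusion weights.
* **Weighted ensemble** — from-scratch AdaBoost over decision stumps
  (φ_c, τ_c = ½ln((1−φ_c)/φ_c)), a bootstrap random forest with per-node
  feature subsampling, and a Gini (1 − Σ V_χ²) decision tree, fused as
  E_c = τ·E_AB + ρ·E_RF + ε·E_DT with τ+ρ+ε = 1 on the simplex.
* **Evaluation** — accuracy, sensitivity, specificity under stratified
  training-percentage (40/50/60/80/90%) or k-fold (2–12) protocols, with
  deterministic seed derivation and byte-reproducible reports.
* **Synthetic data** — seeded EEG records with planted preictal signatures
  (elevated delta/theta, 3 Hz spike–wave bursts, 1/f background) and
  tabular datasets with known informative columns, so everything is
  testable without downloading clinical databases.

## Worked example

Generate a 20-minute two-channel synthetic record with one seizure at
900–960 s, run the full pipeline (0–75 Hz preprocessing, 4 s windows,
600 s preictal horizon, 120 s postictal guard, wrapper feature selection,
ensemble training, fusion tuning) and evaluate an 80% training split:

```r
library(hybridseek)

rec_cfg <- synth_record_config(duration_s = 1200, n_channels = 2,
                               seizure_times = list(c(900, 960)),
                               preictal_horizon_s = 600,
                               preictal_delta_gain = 3, seed = 9)
pipe_cfg <- pipeline_config(preictal_horizon_s = 600, guard_s = 120,
                            protocol = "trainpct", train_percentages = 80,
                            select_population = 10, select_iterations = 15,
                            fusion_population = 10, fusion_iterations = 15,
                            rf_trees = 30, seed = 9)
res <- run_end_to_end(rec_cfg, pipe_cfg)
cat(res$report)
```

```
hybridseek metrics report v1
seed 9
protocol trainpct
protocol  value  accuracy  sensitivity  specificity  T_pos  T_neg  R_pos  R_neg
trainpct  80     1.000000  1.000000     1.000000     30.000 21.000 30.000 21.000
```

The record yields 255 labelled 4 s windows (150 preictal, 105 interictal),
each described by 80 features (5 bands × 2 channels × 8 features). On the
held-out 20% (30 preictal, 21 interictal windows) every window is
classified correctly — the planted preictal delta/theta elevation is a
strong, clean signature, so this is an upper bound of what the pipeline
achieves on real EEG, not a clinical estimate. `run_end_to_end()` can also
write the feature CSV, the metrics report, and the serialized ensemble to
an output directory; a thin command-line front end lives in
`inst/cli/hybridseek.R` (`simulate`, `extract`, `select`, `evaluate`,
`run`).

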