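# chiasmnet

Patch-based 3D CNN detection of optic chiasm malformations, with a
synthetic phantom generator for end-to-end validation.

## The problem

In albinism, an abnormally large fraction of optic-nerve fibres crosses to
the contralateral hemisphere at the optic chiasm. This misrouting — a key
diagnostic criterion — is normally assessed with visually evoked
potentials, which demand patient cooperation. The accompanying structural
changes, however, are visible in ordinary T1-weighted MRI: the albinotic
chiasm and optic nerves are **narrower**, the angles between the optic
tracts are **wider**, and the densely packed central crossing appears
**brighter**.

`chiasmnet` is for researchers in neuroimaging / ophthalmic imaging who
want to build, evaluate or probe a classifier for this contrast. It
provides:

* a compact two-stage 3D CNN — a convolutional **encoder** (pretrainable
  as an autoencoder on *chiasm-excluded* patches, so the feature extractor
  never sees the discriminative structure) and a dense **classification
  head** scoring a 24×24×8 mm patch from 0 (control) to 1 (albinism);
* the full **imbalance-aware evaluation protocol**: per fold, disjoint
  TRAIN / DEV_TRAIN / balanced TEST1 / maximally imbalanced TEST2 groups,
  minority upsampling by `round(n_maj/n_min)` with per-epoch augmentation,
  checkpoint selection on DEV AUROC, and a per-fold optimal decision
  threshold maximizing Youden's *J* = TPR − FPR on DEV scores;
* metrics from the confusion matrix (albinism positive),

  accuracy = (TP+TN)/(TP+FP+FN+TN), precision = TP/(TP+FP),
  recall = TP/(TP+FN), F1 = 2·TP/(2·TP+FP+FN),

  plus tie-aware Mann–Whitney AUROC, and fold aggregation with fractional
  averaged confusion matrices;
* **explainable-AI validation**: exact-gradient saliency, gradient×input,
  occlusion maps, a top-k localization score against the true chiasm mask,
  and class-average difference maps;
* a **phantom generator** rendering X-shaped chiasm patches with known
  ground truth (class effects: width ×0.7, tract half-angle +15°, central
  intensity +0.15 by default; Rician noise, rigid jitter, vessel-like
  distractors), written as NIfTI with CSV manifests and JSON truth
  sidecars.

NIfTI-1 I/O is implemented natively (cross-checked against nibabel in the
test suite), so no external imaging stack is required.

## Worked example

```r
library(chiasmnet)

cfg  <- phantom_effect_config()            # default albinism effects
ctrl <- sample_phantom_params(0, cfg, seed = 1)
alb  <- sample_phantom_params(1, cfg, seed = 1)
r    <- render_phantom(ctrl)

tab <- data.frame(sample_id = sprintf("s%04d", 1:1297),
                  label = rep(c(0L, 1L), c(1274, 23)))
upsampling_factor(upsample_minority(tab))

m <- compute_metrics(confusion_counts(tp = 3.125, fp = 0.375,
                                      fn = 0.75, tn = 3.125))
```

Output:

```
control:  width 14.5 mm, height 3.5 mm, tract angle 38 deg
albinism: width 10.2 mm, central boost 0.15, tract angle 54 deg
rendered patch: 24x24x8 voxels, chiasm mask 348 voxels (7.6%)
upsampling factor for 1274:23 -> 55
fold-averaged TEST1 metrics: accuracy 85%, recall 81%, F1 85%
```

The phantom draws show the class contrast (a narrower, more steeply
angled, centrally brighter albinotic chiasm, with 5% between-subject
variation); the upsampling factor is the one implied by a 1274:23 training
imbalance; and the metric line evaluates a fold-averaged balanced-test
confusion matrix — fractional cells are expected after averaging.

A full synthetic experiment (cohort → pretraining → 8-fold fine-tuning →
evaluation → occlusion XAI) is one call:

```r
res <- run_experiment(list(), out_dir = "out", seed = 7)
# or from the shell:
#   Rscript inst/cli/chiasmnet.R run-all --config exp.yaml --out out --seed 7
```

writing per-fold checkpoints, histories and split lists, `metrics.csv`,
`summary.json`, attribution NIfTIs and localization scores under `out/`.
`audit_experiment("out")` re-derives every aggregate number from the
per-fold artifacts.

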