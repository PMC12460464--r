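# fcadapt

Domain adaptation for multi-site functional-connectivity (FC)
classification. `fcadapt` implements a stacked semi-supervised
variational autoencoder with a maximum-mean-discrepancy penalty
(VAE-MMD) for three-way diagnostic classification — typically developing
control, autism, Asperger — from resting-state FC vectors pooled across
acquisition sites and releases, where non-neural site and release
variability otherwise cripples classifiers trained on one cohort and
tested on another.

## Who it is for

Researchers working with multi-site resting-state fMRI cohorts (ABIDE
I/II-like collections, plus control-only cohorts such as HBN or AOMIC)
who need a classifier for a *target* release whose labels are unusable
or unavailable, trained from a labeled *source* release plus the target's
unlabeled data, with the standard comparators (ComBat harmonization, SVM
and MLP baselines) and an interpretable map from classifier weights back
to region-pair connections.

## The model

A subject is an FC vector `x` (upper triangle of the region-by-region
Pearson correlation matrix; 19,900 features for 200 regions), a domain
indicator `d`, and — for labeled subjects — a class `y`. The generative
model is the stacked construction

    p(x | z1, d) p(z1 | z2, y) p(z2),    p(z2) = N(0, I),  p(y) uniform

with inference networks `q(z1 | x, d)`, `q(z2 | z1, y)` and a classifier
`q(y | z1)`. Training minimizes

    -ELBO(labeled) - ELBO(unlabeled, y marginalized under q(y|z1))
      + alpha * CE(q(y|z1), y)
      + beta  * sum_s MMD^2(z1 means of domain s, z1 means of target)

with an RBF kernel (median-heuristic bandwidth) for the MMD. `alpha`
pushes toward discriminative learning; `beta` toward domain confusion.
Auxiliary control-only cohorts join the labeled term with the control
label and add one MMD pair each (transfer learning). ComBat is
reimplemented as parametric empirical-Bayes location/scale harmonization
with a strict fit-on-train / apply-to-test split.

Everything runs on CPU; gradients are hand-derived and verified against
finite differences in the test suite.

## Worked example

A complete source-to-target experiment on a synthetic multi-site cohort
with known ground truth (30 regions, three sites per domain, 60 subjects
per class per domain, site- and release-level effects at their default
strengths):

```r
library(fcadapt)

cohort <- simulate_cohort(sim_config(n_rois = 30, seed = 0))
cfg <- vae_config(input_dim = 435, enc1_dim = 64, enc2_dim = 32,
                  z1_dim = 16, z2_dim = 8, alpha = 1000, beta = 10,
                  epochs = 50, pretrain_epochs = 50, seed = 0)
res <- run_experiment(cohort$features, cohort$manifest, cfg)
res$metrics$target_test
res$kl
```

```
accuracy: 0.6296  macro F1: 0.6287
    class precision    recall        f1 support
  control 1.0000000 0.5555556 0.7142857       9
   autism 0.6153846 0.8888889 0.7272727       9
 asperger 0.4444444 0.4444444 0.4444444       9
[1] 37.27675
```

The target-domain test accuracy (63% against a 33% chance level) is what
the method is about: no target label was used in training — the target
training records enter with diagnosis `unknown` and the labeled-loss
entry points refuse such records, which the test suite checks by
deliberate contamination. Errors concentrate in the Asperger class, the
intrinsically hard boundary. `res$kl` is the Gaussian KL divergence
between source and target latent representations after training; the
same run with `beta = 0` leaves a larger divergence (39.51 vs 37.28) —
the MMD penalty is what pulls the domains together in latent space. On
the no-shift, strong-signal variant of this simulation
(`site_additive_sd = 0`, `domain_additive_sd = 0`,
`site_scale_range = c(1, 1)`) the same configuration reaches 0.93 target
test accuracy.

The same pipeline is scriptable from a shell via the thin wrapper in
`inst/cli/`:

```sh
Rscript inst/cli/fcadapt simulate --out sim --n-rois 30 --seed 0
Rscript inst/cli/fcadapt train --features sim/features.tsv \
    --manifest sim/manifest.tsv --out run --beta 10 --seed 0
Rscript inst/cli/fcadapt importance --checkpoint run/checkpoint --out edges.tsv
```

Subcommands: `simulate`, `extract`, `harmonize`, `train`, `evaluate`,
`importance`, `embed`; every run writes a manifest of resolved
parameters and is byte-reproducible under a fixed `--seed`.

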