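# pvib

Multi-label image classification with a **patch-level variational
information bottleneck (P-VIB)** — a feature-selection layer for 2-D
convolutional feature maps — implemented as a complete, CPU-scale R
toolkit: backbone → bottleneck → channel-attention neck →
class-specific residual attention head at three pyramid scales, a bias
focal loss for imbalanced multi-label targets, rank-based ROC/AUC
evaluation, a seeded training loop with early stopping, and a synthetic
lesion-image generator (with a domain-shifted variant) so that every
experiment runs with zero downloads.

The intended audience is researchers studying information-bottleneck
regularization and domain-shift robustness in medical-image-style
multi-label classification, at sizes a laptop CPU can handle.

## The method

At each pyramid scale, two parallel 3×3 same-padded convolutions map
the feature map F ∈ R^{C×W×H} to a per-position Gaussian posterior
(μ, σ), with σ = exp(log σ) > 0. Training samples the latent map
elementwise by the reparameterization trick,

    z[j,k] = μ[j,k] + ε[j,k] · σ[j,k],   ε ~ N(0, 1),

and penalizes the posterior's divergence from a standard-normal prior,

    Loss_fea^l = (1 / C·W·H) · Σ_{j,k} ( μ² + σ² − 2·log σ − 1 ),

which is twice the per-element Gaussian KL. The total objective is
`Loss_cls + β · Σ_l Loss_fea^l`, where `Loss_cls` is the bias focal
loss (per-class sigmoid; bias α between positive and negative terms,
per-scale focusing exponent λ_l). Elements whose posterior collapses to
the prior carry no information, so the penalty selects informative
image patches; at evaluation the latent equals μ and inference is
deterministic.

## A worked example

```r
library(pvib)

# a seeded 4-class synthetic dataset (one rare class, co-occurring pairs)
sc    <- synth_config(image_size = c(112L, 112L),
                      n_train = 300L, n_val = 150L, n_test = 150L)
train <- generate_dataset(sc, sc$n_train, seed = 1)
val   <- generate_dataset(sc, sc$n_val,   seed = 2)
test  <- generate_dataset(sc, sc$n_test,  seed = 3)

fit <- train_model(train, val,
                   model_config(num_classes = 4, image_size = sc$image_size),
                   loss_config(beta = 0.1),
                   train_config(epochs = 10L, batch_size = 32L, seed = 1L))
fit
#> pvib fit: 10 epochs, best micro_auc 0.8939 at epoch 10

evaluate_model(fit, test)
#> multi-label AUC: macro 0.9380, micro 0.9121 (4 classes)
#> # A tibble: 4 × 4
#>   class  n_pos n_neg   auc
#>   <chr>  <dbl> <dbl> <dbl>
#> 1 class1    55    95 0.972
#> 2 class2    43   107 0.964
#> 3 class3    26   124 0.918
#> 4 class4    12   138 0.899
```

Each class has a distinct lesion signature (a compact bright nodule, a
large faint opacity, a darker hypodense region, a bright textured
mass), so the per-class AUCs measure genuinely different detection
problems; `class4` is the rare one (positive rate 0.05 by default,
0.08 observed here at n = 150).

The fit's per-epoch history is a tibble (`tidy(fit)`), one-line
summaries come from `glance(fit)`, and `autoplot(fit)` /
`autoplot(evaluate_model(fit, test))` draw the loss curves and ROC
curves. `beta_sweep()`, `fraction_sweep()` and
`domain_shift_experiment()` run the bottleneck-weight, dataset-size and
source-vs-shifted-domain studies; `apply_domain_shift()` re-renders a
generated dataset with an aspect-ratio distortion, off-center anatomy
and extra noise while keeping labels fixed.

A command-line entry point wrapping the same functions
(`simulate | train | evaluate | ablate`) ships at
`inst/cli/pvib.R`:

```sh
Rscript "$(Rscript -e 'cat(system.file("cli", "pvib.R", package = "pvib"))')" \
    train --config run.yaml --seed 1 --outdir runs/demo
```

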