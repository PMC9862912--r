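---
title: "Variational Bayesian motor-imagery classification with a reject option"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Variational Bayesian motor-imagery classification with a reject option}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bayesmi)
```

## The problem and the model

Motor-imagery BCIs classify short EEG epochs into imagined-movement
classes. The physiological signature — event-related desynchronization
(ERD) of the mu (8–12 Hz) and beta (13–30 Hz) rhythms — is buried in
broadband noise and varies within and across subjects, so single
predictions deserve an explicit statement of confidence. `bayesmi`
couples a shallow convolutional network, whose square → average-pool →
log activation chain makes it an end-to-end learnable log band-power
feature extractor, with mean-field variational inference over its
weights.

Each convolutional and dense weight carries an independent Gaussian
posterior $q(w) = \mathcal{N}(\mu, \sigma^2)$, with $\sigma =
\mathrm{softplus}(\rho) > 0$ by construction. Training minimizes the
negative ELBO: the categorical cross-entropy of sampled predictions
plus `kl_weight` times the closed-form Gaussian KL divergence to the
prior. Two priors are available:

* **standard**: $w \sim \mathcal{N}(0, 1)$ on every weight, posterior
  initialized at a fresh Glorot draw with small scales;
* **MOPED**: an empirical prior $\mathcal{N}(w_d, (\delta |w_d|)^2)$
  with $\delta = 0.1$ built from the weights $w_d$ of the pretrained
  deterministic network, with the posterior initialized at the same
  location and scale (and the pretrained batch-norm parameters carried
  over). A floor $\varepsilon = 10^{-6}$ protects weights at exactly
  zero; the absolute value fixes the sign that a literal
  $\sigma = 0.1 w_d$ would lose.

Prediction is Monte-Carlo: $T$ stochastic forward passes with fresh
weight draws (batch-norm frozen in inference mode, so the weights are
the only noise source) give a $T \times C$ *predictive stack*; its
column mean $y^*$ is the prediction, its dispersion the uncertainty.
$T = 50$ is the default balance of cost and stability.

## The abstention rule

For predicted class $c = \arg\max y^*_j$, each pass contributes a
margin $d_t = y^t_c - \max_{j \ne c} y^t_j$. If the model is reliable
on this input, the expected margin is positive. Treating the $T$
margins as a sample, the one-sided test of $H_0 : E[d] \le 0$ with
statistic $\zeta = M / (\sigma_d / \sqrt{T})$ rejects $H_0$ — i.e.
*accepts* the prediction — when $M$ exceeds the adaptive threshold

$$T_M = \sigma_d \, z_{1-\alpha} / \sqrt{T}.$$

The threshold adapts per input: consistent passes ($\sigma_d \approx
0$) are almost never rejected, dispersed ones need a larger margin.
Acceptance is *strict* ($M > T_M$), so the degenerate case of
perfectly consistent but non-positive margins ($M = T_M = 0$) is
rejected. The normal quantile follows the published scheme even though
$\sigma_d$ is estimated; `use_t = TRUE` switches to the exact
$t_{T-1}$ quantile, which at $T = 50$ moves the type-I error from
about 0.053 to 0.050 and is otherwise indistinguishable.

The exhaustive baseline (`sweep_threshold`) instead fixes a cut on
normalized predictive entropy $H_n$, sweeping $[0.05, 1]$ in steps of
0.01 on a validation set and keeping the smallest threshold maximizing
the uncertainty accuracy $UA = (N_{cc} + N_{iu})/N$. Both schemes are
reported side by side by `run_experiment`.

## Tunable parameters

| parameter | default | role |
|---|---|---|
| band edges | 4–38 Hz | retain mu/beta, reject drift and EMG |
| EMS decay $\lambda$ | 0.999 | ≈ 4 s memory at 250 Hz |
| clip factor | 6σ | outlier rectification before standardization |
| crop length / stride | 4 s / 8 ms | augmentation grid (563 crops per trial) |
| $\delta$ (MOPED) | 0.1 | prior relative scale |
| `kl_weight` | 1/N_train | mean-field scaling of the divergence |
| $T$ | 50 | forward passes per prediction |
| $\alpha$ | 0.05 | significance of the margin test |

Training defaults (Adam at 1e-3, batch 64, early-stopping patience 20,
learning-rate halving after 10 flat epochs) are declared package
choices: the corresponding experimental settings are not published, so
they are exposed in `training_config` rather than inferred.

## Design choices in genuinely open spots

* **Crop-range reading.** "Crops from −0.5 to 4 s" is read as bounding
  the crop *starts* (563 crops per trial, last start 3.996 s), not the
  whole extraction window (which would give 63). Only the first
  reading places the five central crops (positions 280–284, starts
  1.732–1.764 s) in the mid-trial interval where the per-position
  uncertainty profile bottoms out; both readings are available via
  `crop_start_end_s`. With an even crop count the central window is
  biased one position toward the trial start.
* **Standardization order.** Each sample is clipped using the running
  statistics available *before* it, then the mean and variance are
  updated with the clipped value, and the sample is emitted with the
  updated statistics. The recurrence is checked against a literal
  scalar-loop oracle to 1e−10. A variance floor of 1e−8 guards
  constant rest windows (flagged with a warning).
* **Causal filtering.** The band-pass runs as a single forward pass by
  default — what an online BCI could compute — with a zero-phase
  option (`zero_phase = TRUE`).
* **Average-pool stride 1.** Forced by the printed feature count:
  478 − 45 + 1 = 434, ⌊434/8⌋ · 40 = 2160. All convolutions are
  "valid"; the same arithmetic fixes stride 2 and no padding in the
  temporal convolution.
* **Gradient estimator.** Minibatch gradients use one shared
  reparameterization sample $w = \mu + \sigma \epsilon$ per batch — an
  unbiased single-sample ELBO gradient estimator. A
  perturbation-sharing (Flipout-style) estimator would lower its
  variance at roughly twice the arithmetic; at the problem sizes this
  package targets the plain estimator trains reliably, and the
  contract (unbiasedness) is what the tests pin down.
* **Validation measures the predictive distribution.** A variational
  model's validation loss is the cross-entropy of its Monte-Carlo mean
  prediction (`val_passes` = 10 draws), not of the posterior-mean
  plug-in network: early stopping should track the quantity the model
  actually reports at test time. The deterministic baseline uses its
  single forward pass.
* **Point parameters.** Batch-norm scale/shift are point parameters,
  not variational; dropout (0.5 on the dense input) regularizes only
  the deterministic baseline and is removed in the Bayesian variants.
  Max-norm regularization of the baseline is omitted entirely —
  early stopping suffices at these scales.
* **Trial-level splitting.** Overlapping crops of one trial are
  near-duplicates, so all splits (test holdout, repeated
  train/validation holdouts) operate on trials, stratified by class;
  disjointness is machine-checked every run.
* **Argmax ties** break to the lowest class index and are flagged.
  Scores are clamped to $[10^{-12}, 1]$ inside logarithms and
  $0 \log 0 := 0$; entropies are in bits (base-2 logs).

## The synthetic data, and what it can and cannot show

`generate_eeg` emulates exactly the features the classifier exploits:
band-limited mu and beta oscillations (Butterworth-filtered noise with
set RMS amplitudes) over a white + 1/f background, with the
oscillatory amplitude on the class-assigned channel group multiplied
by $1 - \texttt{erd\_depth}$ during the imagery window (0.5–4.5 s,
0.1-s ramps). Channel groups are assigned round-robin, classes are
balanced and interleaved, and every draw flows from one seeded
generator per call (bit-identical repeats). At `erd_depth = 0` the
class-conditional distributions coincide and any classifier sits at
the 1/C floor.

The generator is *not* biophysically realistic: no volume conduction
or head geometry, no EOG/EMG artifacts, no inter-subject variability,
no non-stationary drift beyond the 1/f background. Passing tests on it
demonstrate that the pipeline recovers a known contrast and that the
uncertainty machinery is calibrated and internally consistent — not
that the published per-subject accuracies on real recordings are
reproduced (those require the original competition data, which the
package deliberately does not download; `trial_set` accepts any
trials × channels × samples array, so a user-supplied reader can feed
real sessions in).

`generate_stacks` draws predictive stacks from a Dirichlet with
concentration $\kappa$ on the true class and 1 elsewhere, giving one
knob that simultaneously moves the mean toward the one-hot vertex and
shrinks dispersion as $\kappa$ grows. A mean-*preserving* dispersion
knob cannot reproduce the intended behaviour of row entropies rising
as the stack gets noisier — Jensen's inequality forces the expected
row entropy of any fixed-mean sampler *below* the entropy of its mean
— so the mean is allowed to drift with $\kappa$; `deterministic =
TRUE` gives the zero-dispersion limit exactly.

## Numerical notes

The forward/backward pass of the network is hand-written in
RcppArmadillo (time × channel × batch cubes, im2col GEMM convolutions,
cumulative-sum average pooling) and verified against central finite
differences to 1e−6 on every parameter tensor. The log activation is
clamped at 1e−6 (clamped entries get zero gradient); batch-norm uses
biased batch variance with momentum 0.1 running statistics and
$\varepsilon = 10^{-5}$.

Test and example problem sizes are deliberately desk-scale — tens of
trials, coarse crop strides (0.25–0.5 s instead of 8 ms), 15-epoch
budgets — chosen so the full suite demonstrates every mechanism in
minutes on one CPU. The directional comparisons (MOPED converging
faster than the standard prior and ending at least as accurate;
selective accuracy exceeding overall accuracy when anything is
rejected) aggregate over three seeded replicates of that scale.

## Known limitations

* The repeated-holdout orchestrator retrains from scratch per
  repetition; at the published scale (16 repetitions, 8-ms crop
  stride, 250+ trials) it is a batch job, not interactive.
* The adaptive scheme considers only the dispersion of the predictive
  stack (epistemic uncertainty); inputs that are out-of-distribution
  but consistently misclassified are accepted with high confidence, a
  property inherited from the underlying test.
* Batch-norm running statistics are restored together with the
  best-epoch weights; no dedicated re-estimation pass over the
  training set is made after early stopping.
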