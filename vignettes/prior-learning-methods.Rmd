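---
title: "Methods: learning stimulus priors in a rate-coded population"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: learning stimulus priors in a rate-coded population}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The scientific question

How can a population of neurons come to represent the prior probability of
stimuli purely from trial-by-trial feedback about its own decisions, with no
explicit probabilistic teaching signal? `priorpop` implements a complete
simulation-and-analysis pipeline for this question: a Poisson encoder
defines the sensory evidence, a small feedforward rate network learns one of
two perceptual tasks under a manipulated stimulus prior, closed-form
Bayesian ideal observers provide the optimality reference, and a set of
representation analyses asks *where* in the learned parameters the prior
ended up.

## Generative model (the synthetic-data module)

Fifty independent Poisson input neurons encode a one-dimensional stimulus
$s$. Neuron $i$ has a Gaussian tuning curve with center $\phi_i$ (50 centers
evenly spaced on $[-20, 20]$, endpoints included) and width $\sigma^2 = 10$;
its expected spike count is scaled by a global contrast $c$:

$$\lambda_i = c\, e^{-(s - \phi_i)^2 / (2\sigma^2)}, \qquad
  r_i \sim \mathrm{Poisson}(\lambda_i).$$

Contrast controls input reliability: more contrast, more spikes, a narrower
decoded likelihood. Two tasks define the stimulus distribution:

* **Classification** — $s \mid C \sim \mathcal N(\mu_C, 25)$ with
  $\mu_1 = -5$, $\mu_2 = 5$ and class-1 prior
  $\pi \in \{0.25, 0.33, 0.5, 0.67, 0.75\}$, realized purely as the
  frequency of each class during training. Contrasts
  $\{0.5, 1.2, 1.9, 2.6, 3.3, 4.0\}$.
* **Estimation** — $s \sim \mathcal N(0, \sigma_s^2)$ with
  $\sigma_s^2 \in \{100, 50, 25, 10, 5\}$. Contrasts
  $\{0.30, 0.72, 1.45, 2.26, 2.86, 3.2\}$.

Choices the task description leaves open, fixed once here: the per-trial
contrast is drawn uniformly from the task's contrast set during training
(no weighting is stated anywhere, and a uniform draw is the natural
unbiased protocol); cues, when present, are shown equiprobably; a single
seedable generator drives each run.

What the generator deliberately does **not** emulate: temporally resolved
spiking, non-Poisson count dispersion, heterogeneous tuning widths, and
stimulus dimensions beyond one. Tests passing on this generator therefore
say nothing about, e.g., codes that decouple spike-count mean from
variance.

## Network and training

The population model is a dense 50 → 200 → output network of rectified
linear units,

$$h^k = \max\!\big[0,\; \mathbf W^{\!\top} \mathbf r + b^k\big],$$

with a two-unit softmax readout (classification, binary cross-entropy
loss) or a single linear readout unit (estimation, squared-error loss,
no output bias — the trainable parameters are exactly $\mathbf W$,
$\mathbf b$, $\mathbf U$, plus the cue parameters below). All parameters
are initialized $\mathcal U(-\sqrt{1/N_{\mathrm{in}}},
\sqrt{1/N_{\mathrm{in}}})$ with $N_{\mathrm{in}}$ the layer fan-in, and
trained by Adam (learning rate $2\times10^{-4}$, $\beta_1 = 0.9$,
$\beta_2 = 0.999$, $\epsilon = 10^{-8}$) on minibatches of 10 freshly
sampled trials. The backpropagation and Adam steps are implemented
directly in R; at this network size a full 100 000-update run takes about
a minute on one core.

In cue experiments every hidden unit additionally carries, per cue, a
multiplicative gain $g^k_{\mathrm{cue}}$ and an additive bias
$b^k_{\mathrm{cue}}$:

$$h^k = \max\!\big[0,\; g^k_{\mathrm{cue}}
  (\mathbf W^{\!\top}\mathbf r + b^k + b^k_{\mathrm{cue}})\big].$$

The gain is treated as a cue-driven modulation **around unity**: it is
initialized $1 + \mathcal U(-\sqrt{1/50}, \sqrt{1/50})$ and learned
freely. This is a deliberate design choice. Initializing the raw gain
near zero instead (i) starts the cue network maximally far from the
cue-free architecture whose neutral gain is 1, (ii) leaves half the
hidden units with sign-flipped drive throughout training, and (iii) in
our runs produces a qualitatively different, gain-dominated cue
mechanism in which subpopulation averages of the cue parameters carry no
signal. A unity-baseline gain is also the standard formulation in the
gain-modulation literature.

### Training budgets

Two budgets are used, stated here as the package's own choice of problem
sizes:

* **Classification networks**: 20 epochs × 1000 iterations. Posterior
  calibration, accuracy orderings and the threshold (bias) mechanism are
  fully expressed at this budget.
* **Estimation and cue networks**: the full 100 epochs × 1000
  iterations. The estimation-side effects live in slowly reorganizing
  tuning-curve geometry: at 20 epochs the population *sparsity* ordering
  across prior widths is still reversed, and it settles into its final
  direction only with continued training. The cue attribution is likewise
  a quantitative comparison of learned parameters and is cleaner at full
  convergence.

A single network per condition is the default; statistical claims about
*equality* (e.g. per-class accuracy symmetry at $\pi = 0.5$) are tested on
a three-seed ensemble, because a single SGD run retains a residual
decision-threshold offset (order ±0.03 in per-class accuracy, persisting
at 100 epochs) that is training noise, not evaluation noise — the
uncertainty scale for such claims must include the between-run component.

## Bayesian ideal observers

For dense, even tuning the population likelihood is Gaussian in $s$:
$\mu_r = \boldsymbol\phi^{\!\top}\mathbf r / \mathbf 1^{\!\top}\mathbf r$,
$\sigma_r^2 = \sigma^2 / \mathbf 1^{\!\top}\mathbf r$. The classification
observer combines this with the class densities and prior odds,

$$d = \frac{2\mu_r(\mu_1 - \mu_2) + \mu_2^2 - \mu_1^2}
           {2(\sigma_r^2 + \sigma_C^2)} + \log\frac{\pi}{1 - \pi},
  \qquad P(C = 1 \mid \mathbf r) = \frac{1}{1 + e^{-d}},$$

and the estimation observer is the precision-weighted MAP estimate
$s_{\mathrm{MAP}} = (\mu_r\sigma_s^2 + \mu_s\sigma_r^2) /
(\sigma_r^2 + \sigma_s^2)$. Numerical conventions:

* **Zero-spike trials** are flagged uninformative; the posterior falls
  back to the prior and the MAP estimate to $\mu_s$ (the correct
  $\mathbf 1^{\!\top}\mathbf r \to 0$ limit; at $c = 0$ these identities
  are exact).
* The prior odds use expected class frequencies,
  $\log N_1/N_2 = \log \pi/(1-\pi)$, since training realizes $\pi$.
* The closed forms assume $\sum_i \lambda_i(s)$ is constant in $s$, which
  holds away from the edges of the tuned range. Package-internal
  brute-force references (`grid_posterior_class1()`,
  `grid_map_estimate()`) integrate the *exact* Poisson likelihood —
  including the sum-rate term — on a 0.01-step grid; on evaluation
  stimuli in $[-10, 10]$ the closed form agrees with them to better than
  $10^{-3}$ (posteriors) and two grid steps (MAP). An additional,
  implementation-independent check against `stats::integrate` lives in
  the test suite.

## Representation analyses

* **Subpopulations**: hidden units are split by preferred class,
  $H_1 = \{k : U_k(C{=}1) > U_k(C{=}2)\}$, ties (a measure-zero event)
  going to $H_2$. Unit-level parameters (bias, column-mean input weight,
  row-mean readout weight) are compared with two-sided Welch tests at
  $\alpha = 0.01$; the mechanism signature is a bias difference with no
  weight differences.
* **Activity statistics**: counts of units with $h > 0$ and mean
  population activity over fresh trials, per contrast and per class /
  ideal-posterior bin (10 equal-width bins) / prior condition.
* **Cue attribution and ablation**: per-cue, per-subpopulation means of
  $g_{\mathrm{cue}}$ and $b_{\mathrm{cue}}$; ablation replaces a
  channel's per-cue values with each unit's across-cue mean, preserving
  average drive while removing cue dependence.
* **Tuning-curve geometry**: each hidden unit's response is mapped on a
  0.25-step grid over $[-20, 20]$, 200 Poisson draws per point at the
  highest contrast (the mapping contrast is not pinned by the task
  definition; the highest level gives the best signal-to-noise),
  smoothed with a 5-point moving average. The peak is the smoothed
  argmax; the maximal-slope location is the midpoint of the largest
  absolute first difference (the "maximum of the slope" wording conflates
  first and second derivatives; the first-derivative reading is used,
  with `slope_method = "max_second_deriv"` available); FWHM interpolates
  the half-maximum crossings and is flagged invalid when either flank
  never crosses. Units with peak mean response $\le 10^{-3}$ are marked
  inactive and excluded. With these settings the extracted slope
  locations are highly repeatable across probe seeds (test–retest
  $r \approx 0.91$ at 200 repeats).
* **Expected vs unexpected units**: active units whose maximal slope lies
  within one prior SD of $\mu_s$ are "expected"; the bias difference
  between groups is tested with a one-sided 1000-shuffle permutation
  test.
* **Bimodality of peak locations**: tested as a bootstrap likelihood-ratio
  comparison of one- vs two-component Gaussian mixtures
  (`mclust::mclustBootstrapLRT`).

## Evaluation protocol

Held-out evaluation uses 1000 freshly sampled trials per (prior,
contrast) cell with dedicated seeds. Estimation-task evaluation is
restricted to $s \in [-10, 10]$; network-vs-MAP agreement is measured on
validation stimuli drawn from the *training prior* (restricted to that
range) at the highest contrast, and the perceptual-bias curve is probed
on a uniform grid over the same range.

## Known limitations

* Under the sharpest prior ($\sigma_s^2 = 5$) stimuli beyond
  $\approx 3\sigma_s$ essentially never occur during training
  ($|s| = 10$ is 4.5 SDs out). The network's output there is
  unconstrained extrapolation: it overshoots *away* from the prior mean
  (bias $\approx +2$ at $s = \pm 10$) while the MAP observer predicts a
  small bias toward it. Bias-direction claims are therefore evaluated
  within the prior's effective support ($|s| \le 3\sigma_s$), where the
  network tracks the MAP curve closely.
* The expected-vs-unexpected bias effect loses statistical power as the
  prior sharpens (the expected group shrinks to ~25 of 200 units at
  $\sigma_s^2 = 5$, where the test is null in our runs); it is strong at
  $\sigma_s^2 = 100$ and present at $\sigma_s^2 = 10$.
* Tuning-curve concentration effects (slope-location dispersion, FWHM
  narrowing across prior widths) reproduce as orderings; their magnitude
  is modest, with many units retaining broad or edge-peaked curves.
* Learning is plain backpropagation; no biologically local rule is
  provided.

## Reproducibility

Every stochastic step takes an explicit seed. `run_experiment()` writes a
config echo (YAML), parameter archive (CSV + JSON sidecar), training log
and analysis tables such that a run is reproducible from the echoed
config alone; `scripts/acceptance.R --seed N --out f.json` re-trains all
study conditions from scratch and writes the headline quantities.
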