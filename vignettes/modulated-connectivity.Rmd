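---
title: "Modulated effective connectivity: model, estimation and validation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modulated effective connectivity: model, estimation and validation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's account of its science: the model and its
assumptions, the estimation procedure and the numerical choices inside it,
what the synthetic generator does and does not emulate, and the known
limitations. Nothing here states an empirical result that the test suite or
`scripts/acceptance.R` does not itself compute.

## The model

Brain recordings taken across labelled states — sedation levels, sleep
stages, pharmacological conditions — are nonstationary in a structured way:
the anatomy is fixed on the timescale of the experiment, while
neuromodulators rescale synaptic efficacies diffusely and slowly. The model
separates these two ingredients. Each channel carries one excitatory and
one inhibitory population (`n = 2c`, excitatory block first), and the
latent activity evolves in discrete time as

$$x_{t+1} = x_t + (W \odot \Gamma_{i(t)})\,\tanh(S x_t + V) - D x_t + C + \varepsilon_t,
\qquad y_t = H x_t + \nu_t .$$

Assumptions, and how they are enforced:

* **Dale-type sign structure.** Excitatory-source columns of $W$ are
  nonnegative, inhibitory-source columns nonpositive. Inhibitory
  connections are local: the $W_{ie}$ and $W_{ii}$ blocks are diagonal.
  Enforced by projection after every gradient step
  (`project_constraints()`).
* **Sparse excitatory wiring.** 75 % of the off-diagonal entries of
  $W_{ee}$ and $W_{ei}$ are structurally zero. For synthetic data the true
  support is known and used; for real data a random support is drawn once
  per study and shared across subjects (`random_support_mask()`).
* **Diffuse modulation.** Each regime's $\Gamma_i$ is nonnegative and
  rank-1 ($\Gamma_i = a_i b_i^\top$, both factors length $n$),
  multiplying $W$ element-wise. A rank-1 field is the natural encoding of
  spatially diffuse gain: each connection's scaling is the product of a
  source factor and a target factor.
* **Invisible inhibition.** The inhibitory half of the lead field $H$ is
  identically zero: inhibitory populations influence measurements only
  through their effect on excitatory dynamics.
* **Known regime labels.** The regime index $i(t)$ is observed (an
  experimental label). Inferring *when* regimes switch is out of scope.

The per-step leak is written $-Dx$ with $D \in (0,1)$. With the $+x_t$
carry term an update $+Dx$ and decay rates near 0.65–0.82 would be
explosive; the leak reading is the stable one and matches the recovered
dynamics. The literal variant is retained behind `decay = "literal"` for
completeness.

Throughout, the covariances are named by role — `process_cov` for
$\varepsilon$, `meas_cov` for $\nu$ — never by one-letter symbols, because
the Q/R lettering convention is ambiguous across sources.

## Parameters that matter

| parameter | meaning | default | why |
|---|---|---|---|
| `S` | activation slope (dimensionless) | 2.5 exc / 1 inh | places typical activity in the curved part of tanh |
| `D` | per-step leak, in (0,1) | 0.65–0.67 exc, 0.80–0.82 inh | stable decay at a 250 Hz-equivalent step |
| `Γ` factors | regime gain | near 1 | modulation rescales, it does not rewire |
| `process_cov` | state noise variance | ≈ 0.25 I | excites the dynamics enough to identify them |
| `meas_cov` | sensor noise variance | 0.25 I | moderate sensor SNR |

## Estimation

`fit_mindy()` is a dual-estimation loop. Per iteration:

1. **Window selection** — a start index uniform over all positions where
   `window_len + freerun_len` samples fit inside one recording segment
   (windows never span session boundaries). Random windows avoid biasing
   the fit toward any one part of the epoch.
2. **Filtering** — an extended Kalman filter over the window, restarted at
   $x_0 = 0$, $P_0 = I$, with the dynamics Jacobian evaluated at the
   current filtered state and the regime-indexed effective connectivity
   selected per step from the labels.
3. **Free run** — the deterministic model iterated `freerun_len` steps from
   the last filtered state, mapped through $H$.
4. **Gradients** — reverse-mode differentiation of
   $$L = \frac{w_f}{Lc}\sum_t \|y_t - H f(\hat x_{t-1})\|^2
       + \frac{w_{fr}}{Fc}\sum_h \|H z_h - y_{L+h}\|^2$$
   through *the complete filter recursion*: the state path, the covariance
   propagation $P^- = F P F^\top + Q$, the innovation covariance inverse
   and the gain. This yields exact gradients for $W$, the $\Gamma$
   factors, $S, V, D, C$ **and** the log-diagonal noise covariances; the
   test suite verifies every gradient against central finite differences
   of the loss itself (agreement at $10^{-8}$–$10^{-9}$ relative). Learning
   the noise covariances by the same backpropagated objective keeps the
   filter calibrated as the model improves.
5. **Update and projection** — one NADAM step, then projection onto the
   constraint set (sign blocks, mask, nonnegative factors, $D$ and $S$
   nudged inside their open ranges).

The loop stops at `max_windows` or when an exponentially smoothed loss
changes by less than `tol` relatively over `patience` windows.

### Numerical and schedule choices

* **Loss weights.** Filter and free-run terms are averaged per
  sample and weighted `filter_weight = 1`, `freerun_weight = 0.1`. The
  one-step innovations carry most of the identification signal; a small
  multi-step term regularises the dynamics without letting the
  predict-toward-the-mean attenuation of multi-step error dominate the
  weight amplitudes.
* **Window lengths.** `window_len = 20`, `freerun_len = 10` — long enough
  for the filter to lock on from its cold restart, short enough that
  thousands of windows cover the epoch many times over.
* **`burnin`.** Optionally, the first few innovations of each window can be
  excluded from the loss; they reflect the cold-start transient rather
  than model fit. The default keeps them (they are harmless for the
  correlation-based analyses and informative for the drive terms only in
  pathological cases); the single-parameter recovery test shows the effect.
* **Learning-rate schedule.** Cosine annealing from `lr = 2e-3` to
  `lr_min = 1e-4` over the window budget, with Polyak averaging of the
  final quarter of iterates: both reduce the stochastic-gradient noise
  floor, which otherwise dominates the error in the small modulation
  deviations.
* **Initialization.** $W$ magnitudes start half-normal with
  `init_w_sd = 0.3` on the excitatory-source blocks, and the diagonal
  inhibitory weights start at typical physiological size
  (`init_wie = 0.4`, `init_wii = 0.66`, negated). The second choice is
  load-bearing: the inhibitory populations are unobserved, so if an
  inhibitory loop starts near zero the filter assigns it no influence, its
  gradient vanishes, and the loop stays dead — analogous to dead units in
  rectifier networks. Starting the loops alive, at the scale the
  constraint structure implies, removes that failure mode. Modulation
  factors start at $1 + N(0, 0.05)$, clamped; $D$ at the block midpoints;
  $S$ at the block defaults; $V = C = 0$.
* **`gamma_ridge`.** The factorisation $W \odot a b^\top$ is invariant to
  rank-1 rescalings shared across regimes ($W \to W \odot uv^\top$,
  $a_i \to a_i / u$, $b_i \to b_i / v$), so that direction of parameter
  space carries no data gradient and would otherwise accumulate a random
  walk. A weak quadratic pull of the factors toward 1
  (`gamma_ridge = 0.1`) pins the gauge at the no-modulation point without
  constraining the data-identified effective connectivity.
* **Degenerate inputs.** Singular innovation covariances, non-finite
  states or non-finite losses abort with the offending step or window
  index; windows that cannot fit in any segment are an error at selection
  time.

### What is and is not identifiable

Three soft directions deserve explicit mention, because they shape how the
outputs should be read:

1. **The scalar Hadamard gauge** $( \gamma W, \Gamma/\gamma )$: harmless
   for Pearson-correlation analyses and cancelled in regime comparisons.
2. **The rank-1 Hadamard gauge** above: suppressed by `gamma_ridge`.
3. **The inhibitory amplitude gauge**: the scale of an unobserved
   inhibitory population trades off against its row of $W_{ei}$, its
   $W_{ie}$ entry and its slope, anchored only by the curvature of tanh
   and the known process-noise scale. This is the slowest direction of the
   fit and the main reason the EI block recovers slightly worse than the
   EE block.

## The synthetic generator

`generate_ground_truth()` produces labelled recordings with the structure
the estimator assumes: excitatory-source blocks built as sparse + low-rank
+ diagonal ($W_s + W_{l1} W_{l2}^\top + \mathrm{diag}(w)$, entries from
cubed-uniform draws; 75 % off-diagonal zeros applied after completion, with
the mask kept as ground truth), negative diagonal inhibitory weights,
fixed slopes (2.5/1), decays 0.65–0.67 and 0.80–0.82, rank-1 modulation
matrices from near-unity factor vectors (regime mean $\mu_i \sim N(1,0.1)$;
uniform- or normal-spread branch with equal probability), a slow HMM over
regimes (diagonal transition probability ≈ 0.999, uniform initial
distribution; rows renormalised since the nominal construction sums to
$1 - 0.001/nS$), a standard-normal excitatory lead field, and diagonal
noise covariances (process $(0.2 + 0.1U)I$, measurement $0.25 I$).
Unstated pieces are package choices, configurable in
`synthetic_config()`: the $W_{ie}$ magnitudes reuse the sparse-entry
distribution shifted by 0.2, the $W_{ii}$ magnitudes reuse the
excitatory-decay distribution, and the diagonal of each excitatory block
reuses the sparse-entry distribution.

What it deliberately does **not** emulate: volume-conduction artefacts and
line noise, non-Gaussian or nonstationary noise, conduction delays,
unlabelled or mislabelled regime switches, electrode drift. Passing the
recovery suite therefore demonstrates that the estimator inverts the
model class it assumes at realistic noise levels — not that real EEG
satisfies those assumptions.

Default sizes: `c = 10` channels (20 populations) and `T = 20000` steps
are the package's standard study conditions, used by the tests and the
acceptance script; `c = 20` mirrors a clinical EEG montage and needs a
proportionally larger window budget.

## Validation design

* **Recovery**: sample a model, simulate, fit from random initialization
  (true lead field and noise covariances used as initial values, true
  support mask applied), then Pearson-correlate fitted against true blocks
  after truth masking, including the shared structural zeros — medians and
  IQRs over replicates (`recovery_experiment()`).
* **Noise robustness**: the same experiment with the generator's
  *measurement* covariance swept over $(0.05..10)I$. The measurement axis
  is the one that masks information: raising the *process* covariance
  excites the latent dynamics and, empirically, recovery does not degrade
  — a property the noise-sweep documentation states explicitly
  (`noise_sweep()`).
* **Reliability**: temporal split-halves within each regime block,
  within- vs across-model correlation, one-sided rank-sum test
  (`split_half()`, `reliability_stats()`).
* **Modulation analyses**: impact matrices $W \odot (\Gamma_j - \Gamma_i)$
  for temporally adjacent regimes, per-target (row-wise, since row $i$ of
  $W$ drives population $i$) summaries over mask support, pooled
  distribution statistics, and a balanced two-way fixed-effects ANOVA of
  post-synaptic modulation against channel and state with the baseline
  state excluded (its modulation is pinned at 1).

## Known limitations

* Recovery of the modulation matrices is bounded by the accuracy of $W$
  and by each regime's true modulation spread: a regime whose factor
  spread is a few percent carries little recoverable structure at these
  data sizes, and its correlation with truth is accordingly noisy.
* The unmodulated single-regime fit and the modulated fit recover the
  baseline weights at similar quality under these conditions; the
  separation between them reported at much larger training scales is not
  resolved at the reduced problem sizes the package uses by default.
* High measurement noise degrades recovery gracefully rather than
  catastrophically; the filter re-weights toward its dynamics prior as
  the sensors become uninformative.
* One excitatory and one inhibitory population per channel; no conduction
  delays; no continuous-time variant; no GABAergic subtypes.
* EEGLAB `.SET` input is not supported (MATLAB container); use EDF/BDF.
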