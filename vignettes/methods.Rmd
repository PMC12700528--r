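---
title: "Simulation-based inference for whole-brain network models: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Simulation-based inference for whole-brain network models: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(brainsbi)
```

# The inference problem

A whole-brain network model places a neural mass model — a low-dimensional
dynamical system for the averaged activity of a brain region — at every node
of a structural connectome and couples the nodes through its weighted edges.
Given a recording (regional EEG/MEG-like activity, a seizure envelope, or
BOLD), the scientific question is inverse: which control parameters (global
coupling, regional excitability, synaptic counts, conduction velocity, ...)
could have produced it, and with what uncertainty?

The likelihood of such models is intractable: the data depend on the
parameters through long stochastic simulations. The package therefore
implements *simulation-based inference* (SBI): draw parameters
$\theta_i$ from a prior $p(\theta)$, simulate data $x_i \sim p(x \mid
\theta_i)$, reduce each simulation to a low-dimensional feature vector, and
train a conditional density estimator $q_{F(\phi, x)}(\theta)$ — a
normalizing flow — by minimizing the negative conditional log-density

$$\mathcal{L}(\phi) = -\sum_{i=1}^{N_{sim}} \log q_{F(\phi, x_i)}(\theta_i).$$

Training is single-round (amortized): one upfront training pass yields an
estimator that maps *any* new observation's features to a posterior without
retraining. Sequential refinement schemes exist but tie the estimator to one
observation and are prone to leaking probability mass outside the prior
support, so they are deliberately out of scope.

# The simulators

Six connectome-coupled neural mass models share one integration contract
(stochastic Heun; per-node counter-based noise streams; divergence checks;
bit-identical results for identical `(params, connectome, seed, dt,
duration)`):

* **Wilson-Cowan** — excitatory/inhibitory firing rates per region,
  sigmoidal transfer (optionally shifted so $S(0)=0$, making the origin an
  exact fixed point), long-range excitatory and inhibitory coupling.
* **Jansen-Rit** — three synaptic populations per region, alpha-band
  oscillations; the observable is the pyramidal potential $y_1 - y_2$.
* **Stuart-Landau** — Hopf normal form per region with *per-pair conduction
  delays* $T_{jk} = d_{jk}/v$; the only model with delays, matching its role
  in inferring conduction velocity.
* **2D Epileptor** — fast-slow seizure dynamics with a regional
  epileptogenicity map $\eta_i$; deterministic (the equations carry no noise
  term; observation noise is a feature-stage concern).
* **Montbrió** — exact mean-field of quadratic integrate-and-fire neurons in
  firing rate $r$ and membrane potential $v$; bistable at nominal
  parameters; noise enters the $v$ equation only, and $r > 0$ is preserved
  (the $\Delta/\pi\tau$ term repels the axis; a step that would cross zero
  is retried once at half step).
* **Reduced Wong-Wang / pDMF** — one synaptic gating variable per region;
  the transfer function $H(x) = (ax-b)/(1 - e^{-d(ax-b)})$ is evaluated with
  a guarded series branch at its removable singularity ($H = 1/d$ at
  $ax = b$); the pDMF parameterization expresses regional $w_i, I_i,
  \sigma_i$ as linear functions of two anatomical maps, compressing
  $3N$ regional parameters into 9 coefficients.

Defaults follow the published parameter tables of each model; priors for
inference are uniform boxes over the documented ranges. Where a nominal
value and a results-section prior disagree (Wilson-Cowan $g_e$, Jansen-Rit
$C$), the wider results-section range is the default for recovery studies.

Numerical choices worth knowing:

* *Integration steps.* Wilson-Cowan 0.05 (tau units), Jansen-Rit $10^{-4}$ s,
  Stuart-Landau $10^{-4}$ s, Epileptor 0.05, Montbrió 0.01 ms, Wong-Wang
  1 ms — at least 20 steps per fastest local time constant. Halving `dt`
  changes smooth trajectories at second order (measured convergence order
  ≥ 1.7; see the test suite).
* *Delays.* Rounded to the nearest step; the history ring buffer is
  initialized by holding the initial state; `dt` larger than the smallest
  positive delay is a configuration error.
* *Jansen-Rit initialization.* The model's phase space contains, alongside
  the alpha-band focus, a coexisting large-amplitude ~3 Hz spike-wave limit
  cycle. Starting at zero lands in the slow cycle's basin, so each region is
  initialized at its uncoupled equilibrium (damped fixed-point iteration)
  with small seeded perturbations, and the default stochastic drive
  ($\sigma = 2\,s^{-1}$ around the mean input $P = 120\,s^{-1}$) is chosen
  to keep the dynamics in the alpha-resonant regime rather than kicking it
  onto the spike-wave attractor.
* *Per-node noise streams.* Each region's Wiener increments come from its
  own counter-based stream seeded by `(seed, node id)`. Consequence: a
  zero-coupling network run is *bit-identical* to isolated single-node runs
  — a strong correctness lever used throughout the tests.

# Hemodynamics

The Balloon-Windkessel model maps a neural drive $x(t)$ to BOLD through the
vasodilatory signal $s$, inflow $f$, venous volume $v$, and deoxyhemoglobin
$q$, with readout $y = V_0\,(k_1(1-q) + k_2(1-q/v) + k_3(1-v))$ and
constants $k_1 = 4.3\,\vartheta_0 E_0 \mathrm{TE}$, $k_2 = \varepsilon r_0
E_0 \mathrm{TE}$, $k_3 = 1-\varepsilon$. The readout equation itself is the
standard one from the hemodynamic-model literature. Two distinct epsilons
appear (neuronal efficacy in the state equation, intra/extravascular ratio
in the readout) and are deliberately separate fields. The hemodynamic
states are integrated at `decimate` × the neural step on block-averaged
drive; since the fastest hemodynamic time constant is ~1 s, a millisecond
step is conservative while avoiding a 0.05 ms integration forced by the
neural clock. BOLD is emitted at the scanner TR.

# Features

Conditioning features are fixed-length, deterministic, and
permutation-equivariant across regions:

* `psd_summary()` — Welch periodogram (Hann taper, 2 s segments, 50%
  overlap): per-region peak frequency/power, total power, spectral centroid
  and bandwidth, band powers. Power-type entries can be log10-transformed
  (`log_power`), which keeps features spanning orders of magnitude
  comparable after z-scoring.
* `stat_moments()` — mean, variance, skewness, excess kurtosis per region.
* `seizure_features()` — per-region total envelope power and onset time
  (envelope: |signal − slow causal moving-average trend| smoothed over 1% of
  the series; onset: first crossing of baseline mean + 3 SD sustained for
  one smoothing window, scanned after the baseline period — the first 10% —
  so single noise excursions never register; sentinel = recording length
  plus one sample if never crossed).
* `fc_matrix()` / `fcd_matrix()` — functional connectivity and its
  sliding-window dynamics; `fcd_fc_summary()` reduces both to off-diagonal
  moments plus leading eigenvalues. Eigenvalues (not eigenvector loadings)
  enter the feature vector because they are rotation- and sign-invariant,
  so train and test featurization are automatically consistent without
  freezing a fitted basis; the sign-normalized leading eigenvectors are
  exposed as attributes for inspection.

Any non-finite feature is a hard error, never imputed; a simulation batch
drops failing rows with a logged count and aborts above 50% failures.

# The density estimators

No deep-learning runtime is involved: the flows, their exact gradients, and
the Adam optimizer are implemented directly in R and verified against
finite differences.

* **MAF** — five masked autoregressive transforms (Gaussian MADE
  conditioners: two hidden layers of 50 tanh units, masks by the standard
  degree construction, context features injected at the first layer), each
  followed by an invertible batch-normalization layer, with
  dimension-reversing permutations between transforms. The log-scale output
  is soft-capped at ±6 for early-training stability.
* **NSF** — five autoregressive rational-quadratic spline transforms
  (10 bins on [−3, 3], identity tails, softmax/softplus parameter maps with
  minimum bin width and derivative 10⁻³), conditioned by a residual ReLU
  MADE block of 50 units. A learnable per-dimension affine layer follows
  each spline transform: splines on a fixed interval learn conditional
  location/scale shifts slowly, and the affine path restores that degree of
  freedom (the same role LU-decomposed linear layers play in reference
  spline-flow implementations).

Both parameters and features are z-scored inside the estimator
(zero-variance features dropped with a logged list); parameters are not
otherwise transformed, so shrinkage and z-score keep their natural-units
interpretation. Training: Adam (learning rate 5 × 10⁻⁴, batch 256), 90/10
train/validation split, early stopping with patience 20 (cap 500 epochs).
Posterior sampling inverts the flow (autoregressive inversion, one
dimension per pass) and rejects draws outside the prior box; acceptance is
reported and a drop below 1% raises a leakage error.

# Diagnostics

For synthetic recoveries with known ground truth $\theta^*$:

* z-score $z = |\bar\theta - \theta^*| / \sigma_{post}$ (accuracy),
* shrinkage $s = 1 - \sigma^2_{post}/\sigma^2_{prior}$ (information gain);
  ideal inference pairs $s \to 1$ with $z \to 0$,
* posterior correlation matrix (degeneracy detection),
* active-subspace sensitivity: $M = E_{p(\theta|x)}[\nabla_\theta p\,
  \nabla_\theta p^\top]$ estimated over posterior draws with
  $\nabla p = p \nabla \log p$; log-density gradients use central finite
  differences (step 10⁻⁴ × prior width), and density values are normalized
  by their posterior-sample mean because $M$ is scale-sensitive and the
  flow's density is otherwise arbitrary up to feature standardization
  constants. Eigenvalues are clipped at zero; the eigendecomposition
  reconstructs $M$ to 10⁻⁸ relative error.

# The synthetic study conditions

All experiments are fully in-silico: a synthetic connectome stands in for a
tractography-derived one. Weights are symmetric, zero-diagonal, log-normal
(μ = 0, σ = 1) with a requested edge density (default 0.35), max-normalized;
distances are Euclidean between centroids placed uniformly in a 150 mm cube.
What this emulates: heavy-tailed weights and distance structure. What it
does not: community/hub organisation, homotopic connections, tract-length
vs Euclidean discrepancies, or subject-level variability — so passing
recoveries demonstrate the method's internal consistency at realistic
scale, not performance on empirical connectomes.

The bundled recovery presets reproduce the published in-silico studies at
desk scale — 20 regions and a few-thousand-simulation budget (the original
studies use 88 regions and budgets up to 500 k). Scaled-down problem sizes
(durations, sampling rates) per preset:

* *Stuart-Landau* (θ = G, V): 12 s of activity at dt = 0.1 ms, output
  thinned to 1 kHz; per-region log band powers (twelve 5–20 Hz-wide bands
  up to 80 Hz) from 1 s Welch segments. At G = 350 the diffusive delayed
  coupling overdamps the 40 Hz resonance, so the conduction velocity is
  encoded in fine low-frequency spectral structure; the long window tames
  realization noise in those bands. 2 k simulations.
* *Jansen-Rit* (θ = C, G): 3 s at dt = 0.1 ms; per-region spectral
  summaries with alpha-centred bands. 2 k simulations. The global coupling
  is expected to stay poorly constrained — network input barely shifts the
  regional rhythm — and the recovery checks reproduce exactly that
  asymmetry.
* *Epileptor* (θ = G, η₁..η₂₀): 2 EZ regions planted at η = −1.6 on the
  connectome's two strongest hubs, 3 PZ at η = −2.2 on their most strongly
  connected neighbours (propagation needs white-matter routes from the
  focus), healthy η = −3.65; τ = 90 ms; all regions start from a common
  hyperpolarized state (x = −1.9, z = 6.5) so that each region's
  time-to-seizure is governed by its own excitability and recruitment;
  additive observation noise (SD 0.05) on the traces; features are
  per-region envelope total power and onset. 3 k simulations.
* *Montbrió → BOLD* (θ = G, η homogeneous): 20 s of neural activity at
  dt = 0.1 ms, Balloon-Windkessel at 2 ms on the block-averaged rate, TR
  0.5 s; features are BOLD moments plus FC/FCD summaries (window 16 TR,
  stride 4). 2 k simulations.

Each preset's posterior is sampled 10⁴ times and scored with the
diagnostics above; `run_recovery()` writes dataset, estimator, report, and
a manifest of every derived seed, and re-running with the same master seed
reproduces the report bit-for-bit.

# Known limitations

* The R-native flows train comfortably at the feature dimensions used here
  (tens to a few hundred) but are not a GPU stack; half-million-simulation
  budgets are out of desk scale.
* Sensitivity analysis uses finite-difference gradients of the flow density;
  for very peaked posteriors the step (10⁻⁴ × prior width) can matter.
* The Epileptor study conditions plant the pathological regions on
  well-connected nodes; on a connectome whose EZ is weakly connected,
  propagation-zone recruitment (and hence its recovery) can fail — that is
  a property of the model, faithfully reproduced.
* NPZ storage covers numeric arrays only (float64/int), stored
  uncompressed; richer R objects go through RDS.
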