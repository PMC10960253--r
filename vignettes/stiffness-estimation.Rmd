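---
title: "EMG-driven estimation of joint, muscle, and tendon stiffness"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{EMG-driven estimation of joint, muscle, and tendon stiffness}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(emgstiff)
```

## The model

`emgstiff` estimates ankle torque and stiffness at three anatomical levels
— joint, muscle, and tendon — from two non-invasive inputs: normalized EMG
envelopes and the ankle angle. The plant is a three-muscle model of the
triceps surae (medial gastrocnemius GM, lateral gastrocnemius GL, soleus
SO), each muscle a Hill-type fiber in series with an elastic tendon.

Per muscle–tendon unit (MTU), the per-sample pipeline is:

1. **Activation dynamics.** The envelope $u \in [0,1]$ maps to activation
   $a = (e^{Au}-1)/(e^{A}-1)$ with a shape factor $A \in (-3,0)$. The
   endpoints are fixed; more negative $A$ amplifies low excitations. For
   $|A| < 10^{-6}$ a series expansion avoids the 0/0 limit.
2. **Kinematics.** A constant Achilles moment arm $r = 51.3$ mm maps the
   dorsiflexion-positive ankle angle $\theta$ linearly to MTU length,
   $\ell^{MTU} = \ell^{MTU}_{ref} + r(\theta - \theta_{ref})$, anchored at
   the reference posture of 10° plantarflexion (the movement center).
   Angle-dependent moment arms and spline MTU kinematics are deliberately
   out of scope; over the ±20° range studied the linear map is a good
   approximation of the quasi-linear spline kinematics it replaces.
3. **Fiber–tendon equilibrium.** With pennation $\phi =
   \arcsin(\sin\phi_o / \tilde\ell^M)$ (constant muscle thickness), the
   fiber length solves
   $f_t(\epsilon^T) = \big(a\, f_a(\tilde\ell^M) f_v(\tilde v^M) +
   f_p(\tilde\ell^M)\big)\cos\phi$
   by Brent's method. The dimensionless constitutive curves are an
   exponential tendon force–strain curve scaled by a tendon-stiffness
   factor $G_t$, a three-gaussian active force–length curve, a sigmoidal
   force–velocity curve (shortening-positive), and an 11th-power passive
   curve scaled by $G_p$. $G_t$ and $G_p$ expose tendon stiffness and
   muscle passive stiffness to calibration — the package's central
   mechanism.
4. **Stiffness composition.** Analytic derivatives of the curves give
   tendon stiffness $K^T = (F_{max}/\ell^T_s)\,k_t$, fiber stiffness
   $K^M = (F_{max}/\ell^M_o)(a\,k_a f_v + k_p)$, the fiber stiffness seen
   along the tendon line $K^M_{eq} = K^M\cos^2\phi + (F^M/\ell^M)
   \sin^2\phi$, and the series unit stiffness
   $K^{MTU} = (1/K^T + 1/K^M_{eq})^{-1}$.
5. **Joint projection.** $\tau_A = \sum_j r F^{MTU}_j$ and
   $K_A = \sum_j r^2 K^{MTU}_j$; the summed tendon stiffness
   $K_{ATT} = \sum_j K^T_j$ and summed muscle stiffness
   $K_{TSM} = \sum_j K^M_j$ proxy the Achilles tendon and triceps surae
   muscle; the GM muscle–tendon-junction displacement is proxied by the
   zero-centered $\ell^M \cos\phi$ of GM.

We follow the convention that $K_{TSM}$ sums the fiber stiffness $K^M$
rather than the projected $K^M_{eq}$; reference generation and estimation
use the same definition, so the choice is self-consistent (the two differ
by under ~10 % at these pennation angles).

### Numerical choices

**Velocity handling.** The normalized fiber velocity is the backward
difference of fiber length, shortening-positive, with $\tilde v^M = 0$ at
the first sample. Evaluating it *explicitly* (one-sample lag) makes the
force–velocity curve a delayed feedback on the equilibrium and produces a
violent period-two oscillation whenever the tendon is much stiffer than
the fiber — exactly the generic stiff-tendon case. We therefore evaluate
the backward difference *implicitly inside the residual*: at sample $k$
the candidate fiber length itself defines
$\tilde v^M = -(\ell^M - \ell^M_{k-1})/(\Delta t\, v_{max})$. The solve
remains one-dimensional, is unconditionally stable, and the stored
velocities satisfy the backward-difference definition exactly. Since
$f_v$ decreases with shortening velocity, the implicit term makes the
residual more monotone in fiber length, which also helps bracketing.

**Root finding.** The search bracket is $\tilde\ell^M \in
[\max(0.3, \sin\phi_o + 10^{-6}),\ 1.8]$, widened by factors of 1.5 when
the residual does not change sign — upward up to three times, then
downward to the geometric floor $\sin\phi_o$ (extreme trial parameter
sets visited during calibration can put the equilibrium just below the
nominal bracket); fiber-length tolerance is $10^{-12}$ m, leaving the force
residual far below the $10^{-6} F_{max}$ contract. A slack tendon
(negative strain) is evaluated as written — the exponential curve simply
goes slightly negative — and flagged rather than clamped, so the residual
stays continuous; physiological plausibility is enforced by the
calibration penalty instead.

**Out-of-range curves.** All curves are evaluated as written outside
their physiological ranges for the same reason. The descending limb of
the active curve can make $K^M$ (and rarely $K^M_{eq}$) negative; a
non-positive series term is reported as $K^{MTU} = 0$ and flagged.

## Calibration

Seven parameters per MTU ($\ell^M_o$, $\ell^T_s$, $F_{max}$, $A$,
$\phi_o$, $G_t$, $G_p$; 21 in total) minimize
$F_{obj} = p \cdot \mathrm{mean}(E_{active})$, where each $E$ is a mean
squared error normalized by the population variance of its reference
signal. Four calibration types activate references cumulatively: torque
(1), + joint stiffness (2), + GM displacement (3), + tendon and muscle
stiffness as two further terms (4). The penalty
$p = 1 + \gamma\,\overline{v}$ uses a quadratic hinge on fiber lengths
outside $[0.65, 1.35]$ and on negative tendon strain, averaged over
samples and muscles, with $\gamma = 100$ by default; the hinge form and
gain are package choices (only *what* is penalized is dictated by the
model), and both are configurable.

Two tendon priors are supported: the generic stiff tendon
($G_t$ starting at 1, free in $(0.05, 1.5)$) and a compliant Achilles
tendon ($G_t$ starting at 0.278, bounded ±30 %). Remaining bounds are
relative to the initial model: lengths and pennation ±50 %, $F_{max}$
30–250 %, $A \in (-3,0)$, $G_p \in (0.7,1.3)$. Subject geometry (moment
arm, reference MTU length) is not calibrated.

**The optimizer** is a bounded simulated annealer on the unit-scaled
parameter box: randomized coordinate sweeps with per-coordinate uniform
proposal widths adapted toward 40–60 % acceptance (in the spirit of
Corana's adaptive-step annealing), Metropolis acceptance, geometric
cooling (factor 0.9 per level, 3 sweeps per level), an initial
temperature from the objective spread over 100 random probes, and an
elitist restart from the best-ever point at each cooling step. The
default budget is 15 000 evaluations (~0.5–1 min on one core for a 600
sample calibration trial). A single global step width stalled an order of
magnitude higher in objective on some seeds; per-coordinate adaptation is
what lets sensitive parameters (e.g. $F_{max}$) take fine steps while
flat directions keep exploring. Runs are bit-reproducible from the seed.

## The synthetic subject generator

No recordings ship with the package; instead `make_subject()` emulates
the study conditions so every stage is testable end-to-end:

* **Movement**: 40 s sinusoid, amplitude 20° (read as half peak-to-peak),
  0.5 Hz, centered at 10° plantarflexion, with superimposed PRBS position
  perturbations: two levels 0.14 rad apart (symmetric about the sinusoid
  by default), Bernoulli switches every 153 ms, and linear transitions
  rate-limited to 1.75 rad/s. The binary register of the original
  perturbation generator is not public, so seeded Bernoulli switching
  stands in for it; level symmetry and the amplitude reading are exposed
  as options.
* **Excitations**: GM/GL/SO at 20 % MVC plus low-pass-filtered gaussian
  noise (2 Hz cutoff, σ = 0.03 MVC, clipped to [0,1]) — values chosen
  once as a realistic rendering of a subject tracking visual feedback;
  TA near-silent at 1 % MVC with occasional smooth bursts above the 5 %
  threshold to exercise the TA-activity filter.
* **Ground truth**: parameters drawn uniformly ±20 % around nominal
  adult triceps-surae values ($A$ in (−2.5,−0.5), $G_p$ in (0.9,1.1)),
  with $G_t = 0.278$ by default — a compliant-tendon subject. Reference
  torque/stiffness/displacement profiles come from simulating this truth
  model; a noisy variant adds 1 % multiplicative gaussian noise standing
  in for dynamometry and system-identification noise.
* **Session**: 21 trials by default; trials are segmented into
  overlapping three-period realizations (stride one period; 18 per
  trial), TA-active realizations dropped (any-sample exceedance, strict
  threshold), the 200 realizations closest to the 20 % MVC target kept
  (ties broken by trial then period index), and calibration/validation
  sets formed as pointwise ensemble means (15 seeded subsets of 100 for
  validation, drawn without replacement within a subset).

What the generator does **not** emulate: short-range stiffness and
history-dependent muscle behavior, measurement dynamics of the
dynamometer and ultrasound chain, angle-dependent moment arms, and
between-muscle excitation correlations. Passing tests therefore
demonstrate internal consistency of the estimation and calibration
machinery under the study's protocol — not validity against real tissue.

Reference stiffness here comes from the ground-truth model rather than
from perturbation-based system identification (which needs a real limb);
the bootstrap averaging of experimental references is emulated by
averaging noisy replicates.

## Problem sizes used by the test-suite experiments

Self-consistency and prior-sensitivity experiments run on a reduced
synthetic session (2 trials instead of 21, which after segmentation,
TA filtering and ensemble averaging still yields the same 600-sample
calibration trial shape) with the default annealing budget; recovery is
judged on the mean calibrated $G_t$ across the three MTUs, since the
compliant tendon curve is itself defined as an average across muscles.
The full 21-trial session is exercised by the protocol-conformance
checks. These sizes are the package's own defaults for desk-scale
verification; nothing prevents running the full session through
calibration.

## Known limitations

* Torque-only (Type 1) calibration leaves tendon-level parameters nearly
  unidentified under the wide prior — this is not a defect but the
  redundancy phenomenon the multi-level calibration exists to expose:
  with a compliant prior the tendon-level error drops sharply even
  without tendon references.
* With the generic stiff tendon ($G_t = 1$) and large excursions, fibers
  can cross the descending limb fast enough that muscle stiffness goes
  negative at some samples; flagged, and naturally suppressed in
  calibrated models by the penalty.
* The constant-moment-arm map is only as good as its quasi-linear
  premise; outside roughly ±25° of the reference posture a spline map
  should replace it.
* One annealing run per calibration (matching the study's practice) gives
  no convergence guarantee; multi-seed restarts are a flag away and used
  in the package's own experiments.

## A worked example

```{r example, eval = FALSE}
library(emgstiff)

sub <- make_subject(seed = 7, n_trials = 2)          # compliant truth, gt = 0.278
reals <- unlist(lapply(seq_along(sub$trials), function(i)
  segment_realizations(sub$trials[[i]], sub$references$noiseless[[i]])),
  recursive = FALSE)
reals <- filter_ta_active(reals)
sets <- build_sets(reals, n_val_subsets = 2, subset_size = 10, seed = 1)
ref <- make_reference(sub$truth, sets$calibration$trial)   # noiseless reference

res <- calibrate(make_uncalibrated_model(),
                 sets$calibration$trial, ref,
                 calibration_spec(cal_type = 4, tendon_prior = "compliant",
                                  seed = 11))
res
mean(vapply(res$model, `[[`, numeric(1), "gt"))      # ~0.28: truth recovered
```
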