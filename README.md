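# emgstiff

EMG-driven estimation of **joint, muscle, and tendon stiffness** at the
human ankle.

Quantifying stiffness across anatomical levels in vivo normally requires a
robotic manipulator perturbing the joint, dynamometry, ultrasound imaging
of the muscle–tendon junction, and system identification. `emgstiff`
implements the model-based alternative: an EMG-driven musculoskeletal
model of the triceps surae (GM, GL, SO — each a Hill-type fiber in series
with an elastic tendon) that estimates ankle torque and stiffness at the
joint, muscle, and tendon levels from nothing but EMG envelopes and the
ankle angle. It is aimed at biomechanists and neurorehabilitation
researchers who need multi-level stiffness estimates outside a fully
instrumented lab, and at method developers studying how tendon modeling
choices propagate into stiffness estimates.

## The model

Per muscle–tendon unit and sample, excitation $u$ maps to activation
$a=(e^{Au}-1)/(e^{A}-1)$; a constant moment arm $r = 51.3$ mm maps ankle
angle to MTU length; Brent's method solves the fiber–tendon equilibrium

$$F^T = F_{max} f_t(\epsilon^T) = F_{max}\big(a f_a(\tilde\ell^M)
f_v(\tilde v^M) + f_p(\tilde\ell^M)\big)\cos\phi,$$

with $\phi$ the constant-thickness pennation angle. Analytic derivatives
of the dimensionless curves give tendon, fiber, and series MTU stiffness

$$K^{MTU} = \Big(\tfrac{1}{K^T} + \tfrac{1}{K^M_{eq}}\Big)^{-1},
\qquad K_A = \sum_j r^2 K_j^{MTU}, \qquad \tau_A = \sum_j r F_j^{MTU}.$$

Two scale factors expose the stiffness-relevant constitutive curves to
calibration: $G_t$ scales tendon stiffness (1 = the generic stiff tendon;
≈ 0.278 = a compliant Achilles tendon, about four times more compliant)
and $G_p$ scales the passive fiber curve. Seven parameters per MTU are
fitted by bounded simulated annealing against up to five reference
signals (torque, joint stiffness, GM displacement, summed tendon and
muscle stiffness — calibration Types 1–4), with a quadratic-hinge penalty
keeping fibers in $[0.65, 1.35]\,\ell^M_o$ and tendons taut.

A synthetic-subject generator reproduces the study protocol (40 s
sinusoids, 20° amplitude at 0.5 Hz around 10° plantarflexion, PRBS
perturbations of 0.14 rad with 153 ms switching and a 1.75 rad/s velocity
limit, plantarflexor EMG held at 20 % MVC, 21-trial sessions, three-period
realization segmentation, TA-activity filtering, 200-realization ensemble
selection), so calibration and validation are testable with no
experimental data.

## Worked example

Generate a compliant-tendon synthetic subject, build an ensemble-averaged
calibration trial, and calibrate the generic model against the subject's
noiseless reference signals (Type 4: all five signals):

```r
library(emgstiff)

sub <- make_subject(seed = 7, n_trials = 2)        # ground truth gt = 0.278
reals <- unlist(lapply(seq_along(sub$trials), function(i)
  segment_realizations(sub$trials[[i]], sub$references$noiseless[[i]])),
  recursive = FALSE)
reals <- filter_ta_active(reals)
sets  <- build_sets(reals, n_val_subsets = 2, subset_size = 10, seed = 1)
ref   <- make_reference(sub$truth, sets$calibration$trial)

res <- calibrate(make_uncalibrated_model(),
                 sets$calibration$trial, ref,
                 calibration_spec(cal_type = 4, tendon_prior = "compliant",
                                  seed = 11))
res
#> calibration_result: type 4, compliant prior, 15000 evaluations (seed 11)
#>   Fobj 0.107 -> 0.000708
#>   calibration nRMSE (%): tau_a 0.3, k_a 1.0, delta_gm 0.5, k_att 1.4, k_tsm 1.9
mean(vapply(res$model, `[[`, numeric(1), "gt"))
#> [1] 0.2803064
```

The objective falls from 0.107 (uncalibrated model under the compliant
prior) to 7·10⁻⁴; the per-variable nRMSE (root-mean-square error
normalized by reference RMS, in percent) drops to ~0.3–2 % on all five
signals, and the mean calibrated tendon scale, 0.280, recovers the
compliant ground truth `gt = 0.278` almost exactly.
Calibrating the same subject with torque only (Type 1) under the stiff
De Groote-style prior instead leaves the tendon-level error large — the
package's central demonstration that multi-level references (or a
compliant tendon prior) are needed for tendon-level fidelity.

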