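---
title: "Control templates for step-to-step regulation of lateral stepping"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Control templates for step-to-step regulation of lateral stepping}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(latstep)
```

## The modeling problem

A walker on a straight path of finite width must keep both feet on the
path, but infinitely many foot-placement sequences do so: the task is
redundant.  `latstep` implements minimal "control template" models of how
a walker might regulate its lateral stepping from one step to the next,
and the fluctuation analyses used to decide which template reproduces the
step-to-step dynamics that humans actually show on a treadmill.

Three candidate variables can be regulated, all derived from the left and
right lateral foot placements $z_L$, $z_R$ (meters, origin at the path
centerline):

* lateral body position $z_B = (z_L + z_R)/2$, the midpoint of the feet
  and a proxy for the center of mass;
* heading $\Delta z_{B,n} = z_{B,n} - z_{B,n-1}$, a proxy for lateral
  speed (undefined at step 0; all analyses use the length-$(N-1)$
  series);
* step width $w = z_R - z_L$, signed, so crossover steps are
  representable (the default lower step-width limit is slightly
  negative).

Specifying $[z_L, z_R]$ or $[z_B, w]$ is equivalent (an invertible
linear map), so the feet are treated as effectors that enact whatever
regulation acts on $\{z_B, \Delta z_B, w\}$.

## The regulator

Each controlled variable $q$ follows a one-dimensional map across steps,

$$ q_{n+1} = q_n + g\,(1 + \sigma_m \nu_m)\,u(q_n) + \sigma_a \nu_a , $$

with independent standard-normal multiplicative and additive noise
($\nu_m$, $\nu_a$) and a tuning gain $g$ (1 by default).  The control
input minimizing the expected one-step cost
$C = \alpha\,e_{n+1}^2 + \gamma\,u^2$ (goal error versus effort) is
proportional error feedback,

$$ u(q_n) = -\frac{1}{1 + \sigma_m^2 + \gamma/\alpha}\,(q_n - q^*)
          = -G\,(q_n - q^*), $$

so $0 < G \le 1$, decreasing in both multiplicative noise and the
effort-cost ratio.  With $\sigma_m = \gamma = 0$, $G = 1$: the unbiased
limit that corrects the full error in a single step.

```{r gain}
optimal_gain(sigma_m = 0, gamma_over_alpha = 0)     # unbiased limit
optimal_gain(sigma_m = 0.0025, gamma_over_alpha = 0.1)  # baseline
```

### Parameters

| parameter | meaning | default | why |
|---|---|---|---|
| `q_star` | goal value (m) | 0 for $z_B$, $\Delta z_B$; 0.127 for $w$ | path center / straight ahead; 0.127 m is the midpoint of the $\pm5\sigma$ step-width range $[-0.0015, 0.2554]$ m |
| `sigma_a` | additive noise SD (m) | 0.025 | of the order of human step-width variability (SD $\approx$ 0.026 m); adjustable via `calibrate_additive_noise()` |
| `sigma_m` | multiplicative noise SD (–) | `0.1 * sigma_a` numerically | keeps signal-dependent noise an order of magnitude below additive noise |
| `gamma_over_alpha` | effort/error cost ratio (–) | 0.1 | baseline value; sweep variants use 0 and 0.2 |
| `g` | tuning gain (–) | 1 | leaves the derived optimum untouched |

`calibrate_additive_noise()` inverts the stationary AR(1) variance of the
regulated map (coefficient $1 - gG$) to find the `sigma_a` that
reproduces a measured output SD; an optional simulation-based refinement
accounts for multiplicative noise.

## Foot-placement mechanics

The map above governs the controlled variable only; a simulation must
also decide where the feet go.  `latstep` uses the minimal mechanism
consistent with per-step foot-placement series: exactly one foot is newly
placed per step, sides alternate, the stance foot carries over, and the
swing foot is placed at the unique position that realizes the
controller's target for its variable (`swing_foot_for_target()` inverts
the geometry: width control moves the swing foot relative to the stance
foot; position control reflects the target midpoint about the stance
foot; heading control does the same for the target displacement).  All
non-controlled variables then follow passively from geometry, and the
value fed back to the controller on the next step is the *realized*
(post-constraint) one.

Two consequences worth knowing:

* Under width-only control, $\Delta z_{B,n}$ equals
  $\pm(w_{n+1} - w_n)/2$ with alternating sign.  Its DFA exponent
  therefore sits near, but measurably above, $1/2$ (about 0.6 at
  baseline) while $z_B$ is Brownian-like — the qualitative pattern
  expected when neither $z_B$ nor $\Delta z_B$ is controlled.
* Heading is undefined at step 0; the first transition takes
  $\Delta z_B = 0$ (a straight-ahead start), consistent with the default
  initial conditions $z_{B,0} = 0$, $w_0 = w^*$.

### Multi-objective mixtures

Two controllers run in parallel, each with its own noise stream, and
each proposes its own swing-foot placement; the foot lands at the
weighted average $(1-\rho)\,z^{(1)} + \rho\,z^{(2)}$.  Mixing acts on
*placements*, not control inputs, and the two objectives interact only
through the realized geometry.  The headline model regulates position
and step width with $\rho = 0.93$ (93% width, 7% position).

```{r multi}
m <- multi_objective_spec(regulator_spec("z_B"), regulator_spec("w"),
                          rho = 0.93)
tr <- simulate_multi_objective(m, simulation_config(n_steps = 290, seed = 1))
summarize_trial(tr)[, c("sd_w", "alpha_zB", "alpha_w", "slope_w", "slope_zB")]
```

### Constraints

Constrained simulations project each candidate placement onto the
feasible interval: the intersection of the lateral boundary
$[-z_{max}, z_{max}]$ (default 0.885 m, half of a 1.77 m treadmill) with
the interval implied by the step-width limits given the stance foot.
Projection (clamping) was chosen over resampling or rejection because it
is deterministic, never stalls, and flags which limit bound each clamp
for audit; by construction constrained trials have exactly zero
violations.  An empty feasible interval (inconsistent limits) is an
error, not a silent fallback.

## Dependent measures

* **Variability**: sample SD of each series.
* **DFA scaling exponent** `dfa_alpha()`: mean-centered cumulative sum;
  50 segment lengths *linearly* spaced on $[4, \lfloor N/4 \rfloor]$
  (duplicates after rounding removed; a log-spaced option exists but the
  evenly-distributed reading is the default), segments anchored at the
  series start with the tail remainder discarded, per-segment linear
  detrending, and a natural-log least-squares fit of $\log F(j)$ on
  $\log j$.  $\alpha \approx 1/2$: uncorrelated; $> 1/2$: persistent;
  $< 1/2$: anti-persistent; $\approx 3/2$: integrated noise.  Constant
  series are rejected ($F = 0$ has no logarithm).  At $N = 290$ the
  estimator's finite-length bias is within $\pm 0.05$ of the nominal
  values for the white and integrated classes used here.
* **Direct control regression** `direct_control_regression()`: OLS of
  $\Delta q_{n+1}$ on $q'_n = q_n - \bar q$.  For an AR(1) map with gain
  $G$ the population slope is $-G$; slopes near $-1$ mean strong one-step
  correction, near 0 none.  The same construction is applied to the
  heading series itself (i.e. its own first differences regressed on its
  own deviations).

## Model selection machinery

`run_parameter_sweep()` crosses $\rho \in \{0.89, 0.91, 0.93, 0.95,
0.97\}$ with five variants (baseline; $\gamma/\alpha = 0$ and $0.2$;
$\sigma_a$ scaled by 0.9 and 1.1), aggregating each measure as mean and
95% CI ($\pm 1.96\,\mathrm{SEM}$; the CI formula is a package choice) over
`n_trials` trials.  Violation percentages are reported both for the
condition as simulated and for its unconstrained twin, which is what
makes infeasibility visible when constraints are on.
`compare_to_reference()` applies the acceptance rule: a prediction is
consistent with the reference when its mean lies within the reference
mean $\pm$ 1 SD band.  A zero-SD band degenerates to exact equality, by
design.

### The synthetic reference fixture

`generate_reference_fixture()` emulates the *structure* of the human
dataset — 65 trials of 290 steps (13 participants, 5 trials each) — by
simulating the constrained $\rho = 0.93$ position–width model at
baseline, the configuration that reproduces human stepping statistics:
mean step width near 0.127 m with SD near 0.026 m, strongly persistent
$z_B$, weakly persistent $w$, anti-persistent $\Delta z_B$.  It is
synthetic and clearly labeled as such: it carries the model's dynamics,
not a participant's.  In particular it contains no between-participant
heterogeneity, no drift or fatigue, no measurement noise, and its
reference bands are narrower than human bands would be.  Tests passing
against the fixture therefore show internal consistency of the
machinery and the model's qualitative signature — not agreement with any
particular human dataset, which requires supplying analyzed human trials
in the same `stats.csv` schema (the band comparison is source-agnostic).

## Determinism and numerical choices

* Every simulation draws from a noise stream derived from the trial
  seed; reruns are bit-identical, and the session RNG state is restored.
  Streams are keyed by *controlled variable*, so the $\rho \to 1$
  mixture degenerates exactly to the corresponding uni-objective run —
  a testable identity.
* Sweeps and the fixture derive per-trial seeds as documented offsets of
  the base seed, keeping every trial independent and the whole table
  reproducible from one integer.
* The $[z_B, w] \leftrightarrow [z_L, z_R]$ maps are exact inverses in
  exact arithmetic; in floating point each direction rounds once, so
  round trips agree to machine rounding (~1 ulp), which is what the
  tests assert.
* Degenerate inputs fail loudly: constant series for DFA or the
  regression, non-finite placements (with the offending step), empty
  feasible intervals, non-alternating sides in trial files (with the
  row).

Simulated problem sizes mirror the experimental structure throughout:
290 steps per trial, 30 trials per condition (65 for the fixture).
These sizes make every stochastic summary in the tests an average over
at least 30 realizations.

## Limitations

* The models are discrete maps between steps: no within-step dynamics,
  no pendulum mechanics, no sagittal-plane regulation, no muscle or
  neural detail.
* One-step error correction only; humans could correct over multiple
  steps and achieve the same task.
* The foot-placement mechanism (alternating single-foot placement
  realizing the controller target) is the minimal choice consistent with
  per-step placement series; other mechanisms could realize the same
  1D map with different passive dynamics in the uncontrolled variables.
* The fixture is a model of the human data's statistical signature, not
  a surrogate for the recordings themselves.
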