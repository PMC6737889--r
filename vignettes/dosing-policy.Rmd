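---
title: "Learning basal-insulin dose intervals with tabular Q-learning"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Learning basal-insulin dose intervals with tabular Q-learning}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(insulinrl)
```

## The decision problem

Type 1 diabetes requires lifelong exogenous insulin. At quarterly clinic
visits a physician adjusts the patient's daily long-acting (glargine) dose,
aiming to keep glycated hemoglobin (HbA1c) at or below 7%. `insulinrl` casts
this as a finite Markov decision process and learns a dosing policy with
tabular Q-learning from visit-level records:

* **State.** A 4-tuple of discretized clinical factors: HbA1c control band
  (1: ≤ 7%, 2: (7, 9], 3: > 9%), BMI in 17 unit-width bins covering
  18.5–35 kg/m², activity level (1: ≥ 2 sessions/week, 2: fewer), and
  alcohol usage (1: < 2 occasions/week, 2: ≥ 2/week, 3: several times a
  day). This gives 3 × 17 × 2 × 3 = 306 states, indexed 0–305 in a fixed
  mixed-radix order (`state_index()`, `decode_index()`).
* **Action.** One of six dose intervals, in insulin units:
  [6,15), [15,20), [20,30), [30,40), [40,50), [50,100]. Logged doses are
  assigned to actions by half-open partition semantics (`encode_action()`),
  so every dose in [6,100] maps to exactly one action.
* **Reward.** Driven by the change in the HbA1c band between consecutive
  visits: `r = w·(band_before − band_after) + bonus·1[band_after = 1] −
  penalty·1[band_after = 3]`, defaults all 1. Published accounts of this
  kind of reward state only its qualitative shape (reward proportional to
  the HbA1c change, referenced to the controlled target), so the weights are
  explicit parameters (`reward_params()`); because greedy policies are
  invariant to positive rescaling, downstream results do not depend on the
  absolute magnitudes.
* **Learning.** The standard tabular update
  `Q(s,a) ← Q(s,a) + α(r + γ·max_a' Q(s',a') − Q(s,a))`, trained either by
  experience replay over logged transitions (`fit_offline()`) or by
  ε-greedy interaction with a simulator (`fit_online()`). The recommended
  dose interval for a state is the row-wise argmax (`greedy_policy()`), with
  ties broken toward the lowest action and never-visited states flagged.

Two membership semantics deliberately coexist. Training uses the half-open
partition so each logged dose has a unique action. Evaluation asks whether a
physician's dose fell inside a recommended interval, and there the published
test table counts boundary doses (15 units against [6,15); 20 against
[15,20)) as matches — so `dose_in_interval()` is inclusive at both ends.
Each rule is named, documented and tested separately.

## Tunable parameters

| Parameter | Default | Units / range | Role |
|---|---|---|---|
| `alpha` | 0.1 | (0,1] | learning rate; a `1/n(s,a)` schedule is available, under which Q-values converge to expected returns |
| `gamma` | 0.9 | [0,1] | discount weighting future versus immediate reward |
| `epsilon` | 0.1 | [0,1] | exploration probability per step |
| `n_epochs` | 50 | sweeps | replay passes over the logged transitions |
| `q_init` | 0 | value | initial Q-value (any real number is admissible; 0 for reproducibility) |
| `tolerance` | 1e-6 | value | early stop when the largest absolute Q change in a sweep falls below it |

No published values exist for any of these in the clinical setting the
package addresses, so the defaults are conventional tabular-RL practice.
Trajectory ends are treated as terminal (zero bootstrap); argmax ties break
toward the lowest action index so results are deterministic.

BMI values outside [18.5, 35] do occur in real cohorts; the encoder clamps
them to the boundary bins with a warning by default and a strict mode
errors instead (`encode_bmi(policy = "strict")`). The printed definition of
the top BMI bin leaves 34.0 exactly unassigned (the neighboring bin is
[33,34), the top one (34,35]); the package closes the top bin to [34,35] so
the 17 bins tile the range — a one-point repair of an obvious
typographical artifact, verified by a tiling test.

## The synthetic cohort

No clinical data ship with the package; training and validation run against
a seedable synthetic cohort (`generate_cohort()`, `make_simulator()`) that
emulates the *structure* of a basal-insulin EHR extract: 87 patients by
default, 40 quarterly visits each (ten years), each visit recording HbA1c,
BMI, activity, alcohol and the prescribed dose.

The generator has a known ground truth: each state carries a daily insulin
requirement, linear and nondecreasing in the state components
(`true_dose_need()`; 6 units at the reference state, +1.5 per BMI bin, +8
per HbA1c band, +5 for inactivity, +3 per alcohol level, clamped to
[6,100]). Visit-to-visit HbA1c mean-reverts toward a dose-dependent
equilibrium `6.5% + 5 × (relative dose error)`, closing half the gap per
visit, with Gaussian noise (SD 0.3%): a well-dosed patient settles near the
controlled setpoint, a patient dosed at the edge of the ±20% tolerance at a
borderline 7.5%, and a grossly misdosed one in the poorly controlled band.
The expected next HbA1c is strictly increasing in the dosing error, which is
what makes the optimal action identifiable from band-level rewards. BMI
follows a slow random walk; activity and alcohol are fixed per patient
unless `lifestyle_switching` is enabled. Logged doses in generated cohorts
are the true requirement perturbed by ±20% uniform prescriber noise.

In the online simulator the physician is modeled as *titrating* within the
recommended interval: the administered dose is the patient's requirement
clamped into the chosen interval at one-unit resolution. A uniform draw over
the interval was considered and rejected: it systematically favors a narrow
interval adjacent to a wide one (most visibly for requirements in the low
50s under the wide [50,100] interval), so the generator's declared optimal
action would not be the environment's optimal action, defeating the point of
a known ground truth.

What the simulator does **not** model: glucose–insulin physiology (no
meal/exercise events, no intra-day glucose, no hypoglycemia), drifting
insulin sensitivity, adherence, or the state-visitation distribution of any
real clinic. Passing recovery tests therefore shows that the estimator
identifies the dose–response built into the generator — not that the policy
would be clinically adequate.

## Validation surfaces

**Published test table.** A 60-case test table (state levels, prescribed
dose, recommended interval, match flag) ships as a plain-text fixture.
Recomputing boundary-inclusive membership reproduces the recorded match
column on all 60 rows: 53/60 matches (88%). The mean nearest-bound interval
error over the table is 0.8 units; the per-case error (0 inside the
interval, distance to the nearest bound outside) is this package's explicit
choice of error functional, stated so it can be swapped if a different
original form surfaces. One curiosity preserved verbatim: the table's
recommendations are not a function of the state alone (two pairs of
identical states carry different recommended intervals), so a deterministic
policy cannot reproduce all 60 printed recommendations; per-case scoring
can, and does.

```{r table5}
cases <- test_cases()
match_rate(cases)
mean_interval_error(cases)
```

**Bellman fixed point.** On randomly generated deterministic MDPs (up to 10
states and 4 actions, γ ∈ {0.5, 0.9}), offline replay with α = 1 converges
to the fixed point of an independently implemented value iteration to within
1e-6 in the max norm.

**Policy recovery.** `policy_recovery()` trains online against the
simulator and asks, for every state visited at least 30 times, whether the
greedy action is the interval containing the state's true requirement. With
default generator settings this recovers 92–94% of states across seeds.

```{r recovery, eval = FALSE}
rec <- policy_recovery(sim_params(seed = 1))
rec$summary
#> # A tibble: 1 x 3
#>   n_assessed n_recovered recovery_rate
#>        <int>       <int>         <dbl>
#> 1        306         283         0.925
```

The recovery protocol differs from the package training defaults, and
deliberately: broad exploration (ε = 0.5) so every action is sampled often
in every visited state; `1/n(s,a)` step sizes so per-pair values converge to
expected returns; a moderate discount (γ = 0.5) because the optimal action
is discount-invariant under mean-reverting dynamics, while a very small γ is
myopic in the poorly controlled band (one visit cannot separate adequate
from nearly adequate dosing there) and a large γ inflates bootstrap
variance; and 30,000 episodes (~1.2 million visits, about a minute). The
residual non-recovered states are almost entirely those whose requirement
lies within a few percent of an interval boundary — there the neighboring
interval's best dose is nearly as good by construction, and the two Q-values
differ by less than the reward noise can resolve at any practical sample
size.

## Numerical and degenerate-input choices

* State indices are 0-based externally (serialization-stable mixed radix,
  HbA1c most significant); action indices are 1-based, as in the interval
  labels.
* `fit_offline()` shuffles the transition set each sweep, seeded; identical
  configurations are bit-reproducible, including written files.
* Terminal transitions bootstrap zero; empty transition sets and empty test
  case lists are errors, single-visit trajectories are skipped with a
  warning, and unvisited states are never silently recommended — they carry
  a `visited = FALSE` flag, a warning in `run_recommend()`, and a separate
  count in evaluation reports.
* Doses below 6 or above 100 units are outside the action support and error
  on encoding; simulated prescriptions are clamped into [6,100].

## Limitations

The package implements the decision layer only: a 306-state discretization
with band-level rewards discards within-band information, offline training
inherits whatever action coverage the logged prescriptions contain (a
cohort of well-dosed patients identifies good actions but cannot rank bad
ones), and plain tabular Q-learning makes no correction for the
distributional shift of offline learning. Diet, stress, adherence, other
insulin types and type 2 diabetes are out of scope.
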