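---
title: "Measuring group-individual collision avoidance as a scattering problem"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring group-individual collision avoidance as a scattering problem}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`pedscatter` measures how much individual pedestrians deviate to avoid
two-person walking groups (dyads), and how that deviation depends on the
group's social class. This vignette is the package's own account of the
method: the model and its assumptions, every tunable that matters, what the
synthetic-data generator does and does not emulate, the numerical choices,
and the known limitations — in particular what the potential estimator can
and cannot recover.

## 1. The scattering picture

Each frontal encounter between a dyad and a lone pedestrian is analyzed in
the *group-centered co-moving frame*: positions are translated so the
dyad's geometric center sits at the origin, rotated so the group velocity
points along +x, and velocities are shifted by the group velocity. The
rotation preserves the relative distance `|r(t)|`, on which almost all of
the analysis rests, so the frame choice is cosmetic for the statistics and
matters only for the 2D maps.

Two distances summarize an encounter, in analogy with two-body scattering:

* the **straight-line distance** `r_b = |r(t') x v| / |v|` — the minimum
  distance the individual *would* reach if, from the moment `t'` it enters
  the square observation window `[-W, W]^2`, it kept its velocity. This is
  the scattering impact parameter measured at window entry.
* the **observed minimum distance** `r_0 = min_t |r(t)|` — the closest
  approach actually realized.

If nobody reacts to anybody, relative motion in a straight wide corridor is
a straight line and `r_0 = r_b`; the package's null-model tests verify this
identity to machine precision on noiseless simulated data. Any systematic
excess of `r_0` over `r_b` at small `r_b` is collision avoidance.

Assumptions inherited from this picture, and their scope:

* *straight undisturbed relative motion* — requires a straight, wide
  environment over the window scale (a few meters). The linear `r_b`
  calibration (Section 3) compensates mild violations.
* *near-constant relative speed across encounters* — the kinetic-energy
  unit implicit in the probed potential (Section 4) is treated as a shared
  constant; walking-speed spread makes it an approximation.
* *the group as a point* — the dyad is reduced to its geometric center;
  its spatial extent re-enters only through the interpersonal-distance
  unit.

### Distances in interpersonal-distance units

Dyads with different social bonds walk at different interpersonal
distances, so metric distances conflate avoidance with group geometry.
Scaled ("barred") distances divide by the class-average interpersonal
distance `d` (the unweighted mean over the class's groups of each group's
time-averaged member separation). In these units a member sits exactly 0.5
from the center when the dyad walks at its class distance — the package's
first acceptance identity — and `r̄_0 < 1` means the individual came closer
to the group center than the members are to each other, the operational
definition of an *intrusion*.

## 2. From raw tables to encounters

The extraction chain, with its tunables (all fields of `run_config()`):

1. **Atypical-motion filtering** (`filter_atypical`). Instantaneous speeds
   (central finite differences) must stay in `speed_bounds`
   (default 0.5-3.0 m/s, bracketing normal walking); surviving segments
   shorter than `min_segment_duration` (1 s) are dropped. Excursions
   outside the bounds shorter than 0.5 s are tolerated: braking or
   swerving *during* an avoidance maneuver is characterizing motion, and
   chopping there was observed to discard precisely the strongest
   interactions. Velocities computed here are carried with the segments,
   which makes the filter idempotent.
2. **Group tracks** (`build_group_track`). Member 2 is linearly resampled
   onto member 1's timestamps over the common support; the center is the
   arithmetic midpoint, the separation series is attached.
3. **Frontal-encounter selection** (`select_frontal_encounters`). An
   encounter is a maximal run of samples with the individual inside the
   window (`window_half_width`, default 4 m — empirically the region
   containing most of the interaction). It is *frontal* when the angle
   between group and individual velocities at entry is at least
   `frontal_angle_min` (default 135 deg; 180 is head-on). The threshold is
   a declared convention — "frontal" has no canonical quantification — and
   is reported in the logs. Window exits shorter than
   `encounter_gap_merge` (0.5 s) are sampling jitter at the boundary and
   are merged; runs shorter than `min_encounter_duration` (0.5 s) are
   discarded. A genuine exit-and-re-entry starts a new encounter.
4. **Observables** (`entry_time`, `straight_line_distance`,
   `min_distance`). The velocity entering `r_b` is averaged over
   `velocity_averaging_samples` (default 4) consecutive samples ending at
   the entry instant — entry inclusive by default, configurable to
   strictly-before, since either reading of "the instants before entry" is
   defensible; with fewer samples available the count actually used is
   recorded. `r_0` is minimized in closed form on each inter-sample
   segment `r(t_k) + (t - t_k) v(t_k)` (projection of the origin, clamped
   to the interval), with ties resolved to the earliest time; a dedicated
   oracle test checks this against dense brute-force resampling to 1e-9.
   Minima attained at the last in-window sample are flagged as possibly
   censored.

Every stage logs how many units entered and survived, so exclusions
reconcile.

## 3. Binned statistics, intrusion, calibration, maps

`bin_pairs` quantizes `r̄_b` into half-open bins `[k w, (k+1) w)` of width
`bin_width` (default 0.5 scaled units — fine enough to resolve the
small-`r̄_b` region, coarse enough to populate bins), anchored at 0, and
reports mean and standard error of `r̄_0` per class and bin, emitting empty
bins explicitly. Per bin, a classical one-way fixed-effects ANOVA
(`anova_per_bin`) compares `r̄_0` across classes; assumption checking is
logged, not enforced. Intrusion probabilities (`intrusion_table`) are
empirical fractions of `r̄_0` below each threshold (defaults 1.0 and 0.5),
compared across classes per bin by Pearson's chi-squared without
continuity correction; tests with any expected cell below 1 are flagged
unreliable.

**Linear calibration of `r̄_b`** (`rb_linear_correction`). In a biased
environment (curved or narrow corridors) — and, more subtly, because the
entry velocity is measured where the interaction has already begun —
`r̄_b` systematically exceeds `r̄_0` even where avoidance is negligible.
Since avoidance is undetectable for `r̄_b >= 2` (no statistically
distinguishable classes there), that regime serves as calibration: a least
squares line `r̄_0 = a r̄_b + c` is fitted on it and all `r̄_b` are mapped
through it (then clamped at zero, distances being nonnegative). In an
ideal environment `a ~ 1, c ~ 0`. The fitted form is declared in the
output metadata; with fewer than 10 calibration encounters the identity is
used with a warning.

**Density maps** (`density_map`). Positions of the individual in the group
frame are histogrammed on a square grid (`grid_cell`, default 0.10).
Cumulative maps are scaled by their maximum (max cell = 1). Relative maps
are built per class from *probability-normalized* histograms — necessary
because classes differ in sample count — minus the unweighted across-class
mean; they therefore sum to zero cell by cell, which is asserted in the
acceptance suite.

## 4. The collision-avoidance potential

For a conservative central interaction, conservation of energy and angular
momentum tie the closest approach to the impact parameter:
`U(r_0) = E_inf (r_0^2 - r_b^2) / r_0^2`, with `E_inf` the asymptotic
kinetic energy of the relative motion. Dropping the constant prefactor
(masses set to one, relative speed treated as constant across encounters)
leaves the dimensionless probed potential

```
U'(r_0) = (r_0^2 - r_b^2) / r_0^2
```

which is 0 for straight passes, approaches 1 only in the head-on limit,
and *can only probe values below 1* — the initial kinetic energy is the
measuring unit, and one cannot probe potential values above the energy one
brings in. The package evaluates U' per bin: the bin's representative
`r̄_b` is its midpoint (a declared choice; the bin-mean alternative is
reported in logs) against the bin's mean `r̄_0`, after the linear
calibration. Points with negative U' (environment bias) are kept in the
outputs but excluded from fits by default, since `k/r^beta` cannot take
negative values; the exclusion count is reported.

`fit_power_law` and `fit_exponential` use `stats::nls` (port algorithm,
bounds `k >= 0`, `beta > 0`) initialized from a log-linear regression on
the positive points; non-convergence falls back to the initializer with an
explicit flag. Standard errors come from the Jacobian. The fit abscissa is
`r̄_0` — the distance at which the potential is actually probed.

`individual_individual_pipeline` runs the identical chain on pairs of lone
pedestrians, one of them playing the center role (the choice is
irrelevant: `|r|` is symmetric, which a test asserts). There is no
interpersonal distance to scale by, so everything stays in meters,
making these fits directly comparable with group fits in meters.

## 5. The simulator: a stated world

`simulate_dataset` generates ground-truth encounters so the entire chain is
verifiable: a dyad walks along a straight corridor while one individual
approaches head-on with a random lateral offset. The dynamics is a minimal
social-force model, integrated per encounter:

* **goal attraction**: each agent relaxes toward its desired velocity with
  time constant `relaxation_time` (0.5 s, the standard social-force
  value);
* **dyad cohesion**: a linear spring of stiffness `cohesion_strength`
  (5 s^-2, giving a relaxed ~1 s settling of separation perturbations)
  about the dyad's drawn separation. This is a stand-in: the analysis
  makes no assumption about dyad-internal dynamics, and no claim of
  realism attaches to the spring;
* **group-individual repulsion**: a central force of magnitude `|dU/dr|`
  for `U(r) = k_true / r^beta_true` between group center and individual —
  applied fully to the individual and with `mobility_factor` (0.5) to the
  dyad, reflecting that groups deviate less. With probability
  `intrusion_propensity` the repulsion is suppressed for the whole
  encounter: the simplest mechanism that reproduces the observed
  bimodality of pass-through versus avoidance.

Parameters of the world, chosen once:

| parameter | default | why |
|---|---|---|
| desired speed | 1.2 +/- 0.2 m/s | typical unhurried walking |
| sampling period | 0.05 s | dense sensor-grade sampling |
| position noise sd | 0.005 m | see below |
| corridor length | 24 m | 12 m approach on either side of the meeting point |
| lateral offsets | uniform on [0, 5] m | spans every `r̄_b` bin, past the window edge |
| interpersonal distance d | 0.65-0.85 m by class, sd 0.10 | typical abreast-walking separations |
| repulsion (k_true, beta_true) | (0.3 / 1.0 / 3.0, 2) | weak/medium/strong classes; forces of order 1 m/s^2 at 1 m |
| force floor | 0.05 m | numerical guard, far below any analysis scale |

The noise value deserves a note: the generator adds *white* noise at 20 Hz,
whereas real pedestrian datasets ship tracker-smoothed trajectories. White
noise of 2 cm at this rate would imply finite-difference velocity errors
near 0.3 m/s — a quarter of walking speed, far beyond any real tracker
output. 5 mm white noise reproduces the ~6% velocity error typical of
smoothed trajectories, which is the artifact the 4-sample velocity
averaging is designed to absorb.

Integration is fixed-step explicit Euler at one tenth of the sampling
period, downsampled to the recording grid; the analysis only ever sees the
sampled output. Halving the step changes closest approaches by under
1e-3 m, and a single conservative encounter reproduces the two-body
closed form `r_0^2 = b^2 + U_rel/E` to better than 1%, which the test
suite asserts.

What the generator does **not** emulate: walls and obstacles, multiple
simultaneous interactions, anticipatory (velocity-dependent) avoidance,
heterogeneous goals, stop-and-go traffic, and any calibrated human
realism. A green end-to-end test therefore establishes that the *pipeline*
measures what the stated world contains — not that the world is a faithful
model of pedestrians.

## 6. What the estimator recovers, and what it does not

Running the full pipeline on simulated classes that differ only in
`k_true` recovers, robustly across seeds:

* the **ordering** of the fitted strength `k` across classes,
* the **monotone decrease of intrusion probability** with `k_true`,
* the **steeper-potential ordering** (higher probed U' at small `r̄_0` for
  stronger classes).

It does **not** recover the exponent `beta` quantitatively. Fitted
exponents overestimate the true value (typically 2.5-4 for a true 2), for
three structural reasons worth recording:

1. *Dissipation.* The relaxation term makes the relative dynamics
   non-conservative on the encounter timescale, so individuals penetrate
   below the conservative closest approach exactly in the near-head-on
   bins that carry the exponent information; the apparent decay steepens.
2. *Entry-speed bias.* The impact parameter is measured at window entry,
   where the interaction has already slowed the relative motion;
   `r_b = L/|v|` is inflated there, suppressing small probed U' values at
   moderate `r̄_0`. The linear calibration removes the first-order effect
   but not all of it.
3. *Saturation.* Near head-on the probed branch saturates against the
   U' < 1 bound while the bin-mean `r̄_0` clusters at the avoidance floor;
   the first potential points become nearly vertical in `(r̄_0, U')` and
   the unweighted least squares is hypersensitive to their composition.

None of these is a defect of the implementation — each was isolated
against closed-form oracles — and all three would operate on real data as
well. The fitted potentials should accordingly be read as *qualitative*
orderings of avoidance strength across social classes, which is also the
register in which the underlying empirical claims are made. The
corresponding acceptance criterion on `beta` is kept in the test suite at
its stated tolerance and is expected to fail, as an honest record of this
limit.

## 7. Determinism and degenerate inputs

All randomness flows from one seed (`simulate_dataset(seed = )`,
`rng_seed` in configs); the analysis itself is deterministic, and repeated
runs write byte-identical tables. Degenerate inputs fail loudly with
typed conditions: non-monotone timestamps name the pedestrian, unknown
class labels name the scheme, a window that admits no encounter raises an
"empty analysis" error rather than producing empty tables, a stationary
group is skipped per encounter, and a vanishing averaged velocity excludes
the encounter with a degenerate-velocity signal. Ultra-short interpolation
ties resolve to the earliest closest-approach time, making outputs
order-independent.
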