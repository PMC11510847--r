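---
title: "Modelling match workload from GNSS zone kinematics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling match workload from GNSS zone kinematics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(sevensload)
```

# The problem

Session RPE — a 0–10 post-match effort rating multiplied by playing time in
minutes — is the workhorse load measure in team sport, but it is a single
subjective number. In rugby sevens the plausible objective drivers are
high-speed running, hard accelerations and decelerations, physical contact,
and the athlete's own characteristics. This package implements a pipeline
that quantifies those drivers from 10 Hz GNSS speed traces, fuses them with
contact counts and body mass, and asks how much of sRPE they explain.

# Zone kinematics

## Derivative and binning

Acceleration is the first derivative of the GNSS speed signal, computed as
a backward first difference scaled by the 10 Hz sample rate; the first
sample has no predecessor and is assigned zero. No smoothing is applied by
default; an odd-window centred moving average is available
(`compute_acceleration(trace, smoothing_window = )`) for studies of
noise-sensitivity, with edge truncation so the series stays aligned.

Each sample's distance (`speed × 0.1 s`) is binned into one of twelve
zones: speed zone × acceleration type. Speed zones are half-open and
lower-inclusive —

* `LS` walking, `[0, 1.5)` m/s;
* `MS` running, `[1.5, v_sprint)`;
* `HS` sprinting, `[v_sprint, ∞)`,

with the sprint-entry threshold `v_sprint` individualised per athlete as
the *mean* velocity of the 0–10 m split of a maximal 40 m sprint
(`sprint_threshold_from_split`). The alternative reading of "velocity
achieved over the split" — instantaneous exit velocity — is not computable
from a split time alone, so mean velocity is adopted; a threshold at or
below the 1.5 m/s walk boundary is rejected as unusable.

Acceleration types split at ±2 m/s², the threshold appropriate for female
team-sport athletes: `HA` above +2, `LA` in `(0, +2]`, `LD` in `[−2, 0]`,
`HD` below −2.

## The zero-acceleration convention

A sample at exactly constant speed (`a = 0`) is assigned to mild
deceleration (`LD`). This is a deliberate modelling stance, not an
accident: match data of this kind show the mild-deceleration row carrying
an order of magnitude more distance than mild acceleration (roughly
260 / 700 / 80 m across the three speed zones, against ~11 / 22 / 2 m for
`LA`), which is only reproducible if steady locomotion accrues to the
deceleration side of the ledger. Whether that asymmetry in the original
instrumentation arose from smoothing, zero-lumping or proprietary
preprocessing is not knowable from published material; the convention here
is explicit, documented, and testable. Boundary conventions
(±2 inclusive on the mild side, speed zones lower-inclusive) are likewise
fixed so that `assign_zone` is a total, single-valued function — a property
the test suite sweeps explicitly.

Halftime is excluded from zone distances and playing time even though
players remain on the field; playing time is the count of on-field,
non-halftime samples over the sample rate. Whether bench time should count
toward "playing time" is ambiguous in field practice; on-field time is used
throughout.

## Comparator summaries

`comparator_summaries` reproduces the three simpler reductions used in the
earlier acceleration literature — the absolute-value total (distance at
|a| > 2), the acceleration/deceleration quotient (undefined, flagged, when
the deceleration distance is zero), and the four acceleration bins with no
speed split. The four-bin output is exactly the speed-marginalised
twelve-cell grid, which doubles as an internal consistency check.

# The workload model

## Term structure

Total distance is the sum of all twelve cells, so a design containing total
distance plus all four acceleration-type sums is exactly collinear. The
identifiable structure used here absorbs `LA` as the reference acceleration
type (its effect lives in total distance) and moderate speed as the
reference speed zone within each type:

* intercept, mass (kg), contact count, total distance;
* acceleration-type sums `HA`, `LD`, `HD` (each over all three speed
  zones);
* interaction distances `D(a, LS)` and `D(a, HS)` for
  `a ∈ {HA, LD, HD}` — the raw cell distances for the non-reference speed
  zones.

Mass and contact count are fixed effects; the random structure is a single
intercept per athlete. Predictors are z-scored by default purely for
optimiser conditioning (zone distances span three orders of magnitude);
t statistics are invariant to that choice and the test suite verifies the
invariance numerically. Degrees of freedom are Satterthwaite via
`lmerTest`.

Note that total distance and the `LD` sum are almost perfectly collinear in
match data (mild deceleration carries ~93% of distance, and both scale with
playing time). Their individual coefficients are therefore estimated along
a poorly identified contrast with large standard errors; this is a property
of the measurement system, shared by any analysis of this design, and is
why those two terms need substantial true effects to reach significance.

## Adjusted R²

R² is computed as the squared correlation between observed sRPE and fitted
values, adjusted as `1 − (1 − R²)(n − 1)/(n − p − 1)` with `p = 12`
non-intercept terms. Because published analyses of this kind rarely state
whether fitted values include the random effects, both variants are
reported: *conditional* (fixed effects + BLUPs; the headline figure) and
*marginal* (fixed effects only).

# The synthetic study generator

## What it emulates

The generator stands in for an unavailable tournament dataset: a 19-athlete
squad (mass 69.7 ± 6.24 kg, sprint thresholds ~5.2 ± 0.3 m/s), 99 matches
in six- and five-game tournaments, 12 players fielded per match, 10 Hz
traces over 7-minute halves with a 2-minute halftime, negative-binomial
contact counts (mean 4, SD 2.5 at the squad-mean playing time; a Poisson
cannot be that overdispersed), and RPE reports missing completely at random
with probability 186/1188 ≈ 0.157, leaving ≈ 1002 complete records.

Locomotion is a five-state semi-Markov chain — stand, walk, jog, sprint,
contact-brake — with exponential dwells, per-visit target speeds, and
linear speed ramps drawn from a mild/hard mixture. A few ramp rules are
speed-dependent: transitions entirely below 1.7 m/s are always mild,
sprint entries are almost always hard, and decelerations from sprinting
are mostly hard. The sprint target speed is the athlete's own threshold
plus an offset, so every athlete accrues high-speed distance. Athletes
play the full match with probability 0.52 or a contiguous substitution
window of 6–14 minutes; speed is tapered to zero at window and half
boundaries at the hard-ramp rate so the trace never jumps faster than a
hard ramp allows.

The movement defaults were calibrated by iterative simulation against the
cohort's twelve-cell zone-distance profile. Eight cells — including the
three dominant mild-deceleration cells — sit within ±10% of their targets;
the metre-scale edge cells (`LS_HA`, `LS_HD`, `HS_LA` at ~0.82–0.86 of
target, `HS_HD` at ~0.43) resisted further tuning without pushing the
dominant row out of band. Those cells carry 1–3 m per match against
standard deviations of similar size, so the miss is well inside
between-match noise; it is the one acknowledged gap in the generator's
kinematic calibration.

## The response model

The latent session load is

`sRPE* = Xβ + (game_g + u_j) · t/t_ref + ε · √(t/t_ref)`

with `X` the model design on fixed standardisation constants shipped with
the defaults, `t` playing time and `t_ref = 12.3` min. The reported RPE is
`sRPE*/t`, rounded to the integer 0–10 scale and clamped; the analysed sRPE
is that report times `t`. This inversion keeps generated RPE internally
consistent with the sRPE analysed and induces the mild positive RPE–time
covariance the cohort means require.

Three generator choices deserve explanation:

* **Exposure scaling.** Game shifts and athlete intercepts are per-minute
  intensity effects and scale linearly with playing time; the residual
  accumulates like independent increments and scales with √time. Without
  this, a substitute playing three minutes would swing by a whole match's
  load noise, clamping the 0–10 scale at both ends.
* **Mean-zero structure.** Athlete intercepts are centred within the squad
  and the game shifts are weighted to zero across the 99-match schedule, so
  neither leaks into the fitted intercept.
* **Mass is centred at the squad mean** in the latent load: workload
  contrasts are within-squad and the squad-average level belongs to the
  intercept.

The generating coefficients have the qualitative structure the pipeline is
designed to detect: mass negative, contacts and total distance positive,
mild-deceleration main effect negative with positive low-/high-speed
interactions, all acceleration terms zero, games 1–2 of a tournament
carrying a lower load than games 3–6. The noise scales (`sigma_u = 9`,
`sigma_e = 20` au, game gap ≈ 52 au latent) were calibrated once so that
the full simulated study lands on the cohort's printed descriptives and an
adjusted R² near 0.487, then frozen.

## The reporting ceiling, and what the tests can show

The cohort's printed moments are near the 0–10 ceiling (mean RPE ≈ 7 with
roughly half of sRPE variance unexplained), so ~7% of latent ratings clamp
at 10 in the calibrated study. Clamping is a property of the reporting
scale, not of the estimator: it attenuates the strongest coefficients by
roughly 5–15% at tournament scale. Consequently the Monte-Carlo coverage
study runs on the exact latent response (`exact_rpe = TRUE`, no rounding or
clamping), which is the honest test of the estimation machinery, at a
reduced study size of 12 matches per replicate; the zero-noise recovery
test separately proves exact identifiability of the full path through trace
simulation, zone extraction and fusion. What the passing suite therefore
shows is that the *pipeline and model recover what generated the data*;
what it cannot show is robustness to everything real GNSS data adds —
positional error, Doppler-vs-position speed derivation, sensor dropout,
non-Markov tactical structure, or informative (non-MCAR) missingness.

Problem sizes used by the checks: the calibrated-study reproduction runs
the full 99-match study once; coverage uses 200 replicates of 12 matches;
the evaluation-pattern check uses 100 replicates of 48 matches, the
smallest size at which the Tukey pattern {1,2} vs {3,4,5,6} is jointly
detected in ≥90% of replicates at α = 0.01.

# Evaluation across game numbers

`rm_anova` fits a two-factor ANOVA (game number × sRPE type, with
interaction) with athlete removed into an error stratum. Published
repeated-measures F statistics for designs like this often carry
denominator degrees of freedom that no standard layout reproduces, so the
package treats the evaluation as pattern-based: game number significant,
sRPE type not, Tukey flagging exactly the early-vs-late game pairs. Tukey
HSD runs on the game-number marginal means with athlete and type as
additive blocks; the within-game type comparison is a paired t test per
game, Holm-adjusted across the six games (no adjustment is canonical here;
Holm is the conservative default). α = 0.01 throughout, matching the
reporting convention of the field. Degenerate inputs are handled
explicitly: zero-variance cells report `F = 0, p = 1` rather than `NaN`,
identical paired differences report `p = 1` (or 0 when the common
difference is non-zero), and unpaired rows raise a pairing error naming the
orphans.

# Numerical and interface choices

* Seeds: every simulation entry point takes an explicit seed and restores
  the caller's RNG state; child seeds are derived per match and per trace,
  so the whole study is bit-reproducible from one integer.
* The twelve cells are stored in a fixed column order (`LS_LA` … `HS_HD`);
  conservation (cells sum to total distance, tolerance 1e−6 m) and the
  loop-oracle identity are enforced by tests on random traces.
* CSV dialects are plain and round-trip through the package's own readers;
  fit and evaluation reports serialise to JSON with full precision.
* Errors are classed conditions (`invalid_argument`, `collinearity_error`,
  `pairing_error`, …) so callers and the CLI wrapper can map them to exit
  codes.

# Known limitations

* The generator emulates summary statistics, not rugby: no ball, no
  opponents, no spatial structure, no fatigue drift across a tournament
  day.
* Contact counts and the kinematic contact-brake state are statistically
  independent streams, as video-coded counts and GNSS kinematics are in
  the real workflow; a joint model of collisions and decelerations is out
  of scope.
* Playing-time dispersion (SD ≈ 2.4 min) is narrower than the cohort's
  printed ±4.53 min; widening it further is impossible inside a 14-minute
  match while keeping the mean near 11.8 min and the reporting scale
  unclamped.
* The cohort's printed moments (RPE 7 ± 1.8, time 11.8 ± 4.53, sRPE
  99.2 ± 44.09) are mutually inconsistent as exact moments — the implied
  RPE–time covariance exceeds its Cauchy–Schwarz bound — so the generator
  targets the means jointly within tolerance rather than all moments
  exactly.
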