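---
title: "Synchronization models for multilevel herds: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Synchronization models for multilevel herds: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(herdsync)
```

## The scientific problem

Feral horses live in a two-layered society: stable units (harems and
bachelor groups) whose members graze within a couple of metres of each
other, aggregated into a herd in which neighbouring units keep a spacing of
tens of metres. Scan observations record, every 30 minutes over a 9-hour
day, each individual's position and whether it is resting or moving. The
question the package addresses is at which social level the resting/moving
rhythm is synchronized: not at all, anonymously with any herd member, only
within units, or herd-wide with unit-mates weighted more strongly.
`herdsync` provides all stages of that analysis: network construction from
positions, synchronization scoring, parameter estimation, a stochastic
multi-agent simulator of seven candidate mechanisms, and a model-ranking
harness.

## The transition model

Agents are binary (resting/moving). For agent `i` with time `dt_i` since
its last state change, the per-minute probability of switching into the
destination state `s` is certain once `dt_i` reaches the refractory period
`dT01_s`, and before that is

`psi_i,s = min{ 1 / (dT01_s - dt_i), drive_i,s }`,

clipped to [0, 1]. The cap term implements a *soft* refractory period:
immediately after a change the agent is nearly insensitive to others
(cap `1/dT01`, i.e. 0.02–0.04 per minute at the field values), and its
susceptibility rises as the refractory period runs out. The drive is the
hypothesis-specific social pressure: the baseline rate `lambda_s` alone
(independent), plus `C` times the count of individuals already in `s`
(anonymous absolute), the ratio of destination to current counts
(anonymous proportional), the association-weighted sums
`sum_{k in s} a_ik` (social absolute, with the network either unit-level
or herd-level), or their ratio (social proportional). A zero proportional
denominator is treated as unbounded drive, so the cap alone applies: the
agent is maximally susceptible when *everyone it is weighted towards* has
already switched.

Three conventions deserve note, all fixed after weighing the alternatives:

* **Destination-state indexing.** All parameters are indexed by the state
  being *entered*: a resting agent faces the moving-destination refractory
  of 25 min and baseline `lambda_m`; a moving agent the 50-min resting
  ones. This is the only convention under which the identity
  `dT01_s = 1/Psi1_s` (50 = 1/0.02, 25 = 1/0.04), the rate identity
  `lambda_s = Psi1_s/N`, and the observation that agents wake up once the
  refractory period expires are simultaneously consistent.
* **Synchronous updates.** All probabilities are computed from the state
  at the start of a minute, then every agent draws independently. This
  makes the dynamics order-independent and exactly reproducible;
  a sequential scheme would make results depend on an arbitrary agent
  ordering.
* **Forced switch at `dt >= dT01`** (not `=` only), guarding against any
  discrete-step overshoot, and initial `dt_i ~ Uniform[0, dT01_dest)`,
  which is the stationary within-bout age distribution and avoids an
  artificial mass switch when the refractory period first expires. Each
  day starts with `round(0.30 N)` resters (37 of 123), the field average.

Default parameters (`modelParams()`): `Psi1 = 0.02 / 0.04` per minute so
`lambda = 1.63e-4 / 3.25e-4`; `C = 0.426 / 0.796` per minute (inverse mean
joiner latencies of 2.3 and 1.3 min); `dT01 = 50 / 25` min; `N = 123`;
540-minute days scanned every 30 min (18 scans). A note on `Psi1` for the
resting destination: the source material prints both 0.030 and 0.02; only
0.02 is consistent with `dT01 = 50` and `lambda = 1.6e-4`, so 0.02 is the
default.

## Network construction

The association threshold is data-driven: pool all within-scan pairwise
distances, choose a histogram bin width by the direct plug-in rule
(`KernSmooth::dpih`, overridable), and take the upper edge of the
minimum-count bin between the two highest local maxima — the nadir of the
bimodal distance distribution that separates intra-unit from inter-unit
spacing. Ties in peak or nadir counts break towards the smaller distance,
making the rule deterministic. With the field bin width of 0.92 m the
nadir bin spans 10.12–11.04 m (printed 10.1–11.0), which is where the
conventional 11 m threshold comes from; whether that threshold should be
the lower or upper edge of the nadir bin is ambiguous in print, so the
upper edge is used and an explicit `threshold` argument overrides it.

Per scan, dyads closer than the threshold are associated, connected
components become cliques (chain rule), and an individual with no direct
neighbour is rescued — joined to its nearest neighbour's pre-rescue
component — when that neighbour is nearer than the second histogram peak
`p2`, else dropped from the scan. The rescue is a single pass; cascading
rescues would make the result depend on processing order. Dyadic weights
are simple ratio indices (joint associations over occasions at least one
was seen), and rows are then scaled so each individual's outgoing sum is
`N` (average weight 1.0). Row normalization makes the network directed
(each row is the influence budget flowing *into* that individual) and
makes the social drive commensurate with the anonymous `C * n_s` when all
weights are equal. The unit-level network zeroes inter-unit weights
without re-normalizing, so the intra-unit relationships are identical
across the unit- and herd-level hypotheses — re-normalizing would
confound the comparison by inflating intra-unit influence in the unit
models.

## Synchronization metrics

* **Synchronization rate**: per dyad, the fraction of scans (both
  observed) spent in the same state. Dyads never co-observed are excluded,
  not zero-filled.
* **Phases**: maximal strictly monotone runs of the per-scan resting
  count within a day; decreasing runs are resting-to-moving phases,
  increasing runs the opposite. Plateaus break runs — the only reading
  under which separate events can be counted. The day's first and last
  scan-to-scan changes are discounted (runs are clipped off them), since a
  change at the observation boundary cannot be attributed to a complete
  phase. A `minJoiners` knob (default 1) sets the minimal per-step
  amplitude for a run to count.
* **Delta-n**: per phase and per 30-minute window from its start, the
  number of individuals switching to the phase's destination state.
* **Latencies**: gaps between consecutive phases (the refractory samples)
  and between consecutive joiners. Scan sampling only brackets a switch
  to within one 30-minute interval, so the `k` joiners of an interval are
  imputed evenly spaced times (`interval/k` apart) — the maximum-entropy
  choice, isolated in one helper so a different imputation can be swapped
  in.

## Parameter estimation

Latency samples are fitted by log-survival regression: the empirical
survivor function is evaluated at the observed values, the terminal zero
point dropped, and a least-squares line fitted to `log S(t)` against `t`;
the absolute slope is the exponential rate. This matches the
survival-curve procedure the field estimates come from, is deterministic,
and is testable against known samples (the package recovers scales of 25
and 50 min within 15% at n = 500). Refractory periods are the fitted
scales of phase-start latencies; mimetic coefficients the fitted rates of
joiner latencies; baseline rates follow from `lambda = Psi1/N` with
`Psi1 = 1/dT01`. Delta-n profiles are summarized by least squares over
the two-parameter family `a x^2 + b x` through the origin (the curve
cannot produce joiners before the phase starts), with the coefficient of
determination computed about the mean.

## Model comparison

Each candidate model is simulated for `nReps` replicate days and compared
to the observed record by four tests: K-S on pooled delta-n towards
moving, K-S on pooled delta-n towards resting, K-S on pooled intra-unit
synchronization rates, and a Mantel test between the across-replicate
mean simulated synchronization-rate matrix and the observed one (9999
permutations by default, one-sided upper p, seeded and reproducible; an
`exact = TRUE` mode enumerates all permutations for small matrices).
Pooling across replicates and averaging the matrix are configurable
choices; both are stated here because the source material does not fix
them. A model beats the independent null on a test by a strictly smaller
D or strictly larger r — ties are not wins — and its score is the
fraction of the four tests won.

## The synthetic-society generator

The generator emulates the statistical structure the analysis relies on,
not trajectories. Per scan, each unit receives an independent centre drawn
from an isotropic bivariate normal with per-axis SD
`interUnitScale/sqrt(2)`, so inter-unit distances are Rayleigh-distributed
with mode `interUnitScale` (default 50 m, placing the inter-unit histogram
peak where field data show it); members scatter around their centre with
SD `intraUnitSpread` (default 1 m, intra-unit mode 1–2 m). Unit sizes are
truncated-Poisson draws adjusted to the exact herd total (123 in 23
units); the size distribution itself is unconstrained by the source
material, so any distribution matching the totals is acceptable. Because
centres resample every scan, units occasionally pass close enough to
chain-merge, producing the small nonzero inter-unit association the
herd-level hypothesis needs: on default data the normalized network shows
within-unit weights of ~16–17, across-unit means of ~0.27 and a
within/across ratio of 50–100, bracketing the field values (19.4, 0.26,
75.9). All randomness flows from one master seed through derived child
seeds (society, positions, states), so identical configurations reproduce
byte-identical outputs.

What the generator does *not* emulate: movement persistence and home
ranges (unit centres are exchangeable across scans), terrain, observation
gaps (every individual is seen in every scan), and any time-of-day
effect. Tests passing on synthetic data therefore validate the pipeline's
mechanics and the model's internal identities, not field realism.

## Numerical choices

* Histogram bins anchored at 0 with edges `k * binWidth`; a distance of
  exactly 0 falls in bin 1.
* Peak detection uses strict local maxima (histogram ends included when
  they dominate their single neighbour); nadir and peak ties break toward
  smaller distances.
* The Mantel p-value is `(1 + #{r_perm >= r_obs}) / (1 + nPerm)` with a
  1e-12 tolerance on the comparison to absorb floating-point ties.
* K-S p-values use the asymptotic two-sample distribution (`stats::ks.test`,
  `exact = FALSE`); ties make them approximate, which is irrelevant to the
  ranking since only D enters the score.
* Row normalization requires strictly positive row sums and names the
  offending individual otherwise; SRI rows of never-observed individuals
  are zero with a warning.
* Degenerate latency classes (fewer than 5 samples, or a survivor
  function with fewer than two positive points) are reported as missing
  rather than fitted.

## Problem sizes

The test suite exercises the full field scale where it matters: the
model-recovery experiment uses 123 agents in 23 units, 4 observation days
(72 scans), all seven models at 20 replicate days each, across 5 master
seeds, with 199 Mantel permutations inside the recovery loop (the score
depends only on r, so the permutation count affects only the reported
p-values; the default elsewhere remains 9999). Oracle-equivalence and
estimator-recovery tests run at the sizes stated above (samples up to 8
for the K-S oracle, matrices up to 5 x 5 for exhaustive Mantel
enumeration, n = 500 for survival-fit recovery).

## A structural finding, and limitations

With the field coefficients, the mimetic drive almost always exceeds the
refractory cap. The cap never exceeds 1, while one average-weight
associate already contributes `C * 1 ≈ 0.4–0.8` and a normalized row sums
to `N`: for the herd-level models, `C * sum_{k in s} a_ik` is of order
10–30 whenever any non-trivial part of an agent's network occupies the
destination state — which, in a 123-agent herd with dense normalized
rows, is essentially always. The `min{}` then always returns the cap, so
herd-level absolute dynamics are *identical in distribution* to anonymous
absolute dynamics (simulated delta-n means agree to three digits, and the
intra-/inter-unit synchronization separation of herd-level simulations is
zero), and bout lengths are near-uniform on `[0, dT01]` for every coupled
model. Two consequences follow and are visible in the test suite:

* A model-recovery experiment with herd-level ground truth cannot single
  out the herd-level models: observed data generated under `herd_abs`
  carries no network signature for the Mantel or intra-unit K-S tests to
  detect, so the corresponding acceptance checks document this
  equivalence rather than pass.
* The unit-level models *are* distinguishable (a zeroed inter-unit
  network makes "no unit-mate in the destination state" a reachable,
  sticky regime), which is why they — and only they — separate intra- from
  inter-unit synchronization in simulation (mean difference ~0.1).

Equivalently: for herd-level mimetism to leave a network signature under
this rule, the weighted drive of a poorly-connected agent would have to
fall below the early-refractory cap `1/dT01 ≈ 0.02–0.04`, which
row-normalized weights rule out by construction. Readers applying the
package to field data should therefore treat the absolute herd-level and
anonymous hypotheses as an equivalence class under the printed rule, and
regard distinctions between them reported elsewhere as depending on
implementation details not derivable from the rule itself. Relatedly, the
forced switch at the refractory boundary makes the independent model a
deterministic rest-25/move-50 clockwork whose 75-minute period aliases
against 30-minute scans; it is anything but quiet, producing the largest
per-window change counts of all models.

Further limitations: agents do not move during simulation, so the network
is static within and across days; there is no environmental forcing or
time-of-day effect; the Mantel test assumes a complete shared id set
(dyads with no co-observation are excluded pairwise); and the even-spacing
joiner imputation compresses latency estimates when cascades are fast —
at scan resolution the survival-fit mimetic coefficient from simulated
data reflects cascade size more than the generating `C` (mean joiner gaps
stay within a factor ~2–3 of `1/C`; the fitted rate does not).
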