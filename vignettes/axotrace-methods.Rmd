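---
title: "Methods: axon direction, burst dynamics and functional connectivity on compartmentalized MEAs"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: axon direction, burst dynamics and functional connectivity on compartmentalized MEAs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(axotrace)
library(dplyr)
```

## The experimental system

`axotrace` analyses spike recordings from hippocampal cultures grown in a
four-compartment device on a multi-electrode array. Each compartment holds
the somata of one sub-region of the trisynaptic loop — entorhinal cortex
(EC), dentate gyrus (DG), CA3 and CA1 — with 19 dedicated well electrodes
per compartment. Neighbouring compartments are joined by microfluidic
tunnels that admit only axons; five tunnels per wall are spanned by a pair
of recording electrodes 0.2 mm apart. Because a propagating action
potential reaches the two tunnel electrodes at slightly different times,
the signed inter-electrode delay reveals both the identity (conduction
velocity) and the travel direction of individual axons.

Feed-forward is defined along the loop EC > DG > CA3 > CA1 > back to EC;
an axon whose spikes hit the upstream electrode first (positive delay) is
feed-forward, a negative delay is feedback. Axons crossing the CA1/EC wall
in the EC-to-CA1 sense are labelled feedback purely for internal
consistency of this convention.

The package starts from *sorted spike times* (a CSV of electrode id and
time in seconds plus a JSON layout). Raw voltage filtering, spike
detection and waveform sorting are upstream and out of scope. All times
are seconds internally; conduction delays are expressed in milliseconds
only at interfaces, because the two scales differ by four orders of
magnitude and a single canonical unit prevents unit bugs.

## Axon identification and direction

For each tunnel, `match_spike_pairs()` pairs spikes across the two
electrodes. A candidate pair is any combination whose signed delay
magnitude lies in 0.2–1.0 ms, the physiological conduction range over
0.2 mm; both signs are admitted. The published description says only that
paired spikes fall in this window, so the pairing rule is a design choice:
we use greedy one-to-one matching by smallest |delay| (ties to the earlier
upstream spike). One-to-one matching enforces the physical constraint that
one spike is one propagation; the greedy order is deterministic and, on
sparse trains, attains the exact maximum matching (the test suite checks
this against an exhaustive bipartite-matching oracle).

The normalized matching index
`NMI = n_paired / max(n_up, n_down)` gates tunnel validity at NMI > 0.2
(strict), which suppresses spurious pairings during high spike rates. NMI
is computed from raw pairable spikes *before* any axon assignment, since
the gate is applied before axon identification.

Valid tunnels get a conduction-delay histogram over ±1 ms. The bin width
is not published; we default to 0.04 ms so that the ±0.16 ms axon merge
radius spans four bins, and expose it as a parameter. Peaks qualify as
axons when the bin count exceeds `mean + 1.9 SD` of all bin counts and
the topographic prominence is at least 12% of the highest bin. The
"1.9 standard deviations" baseline is not fully specified in the source
analysis; we interpret it as a global mean + 1.9 SD threshold over the
histogram's bins, the simplest reading consistent with an empirically
determined threshold. Prominence is computed with the histogram treated
as zero outside the delay window (there are no pairs there by
construction), which keeps near-window-edge peaks detectable. Qualifying
maxima within 0.16 ms of a taller one are merged into it; each pair is
then assigned to the nearest surviving peak within 0.16 ms. Peaks faster
than the 0.2 ms window edge are admitted down to 0.12 ms (a configurable
flag, on by default): sufficiently fast conduction is genuine if a clear
peak stands there. The peak's sign gives the axon's direction.

One numerical caveat: with a 0.04 ms bin width, two planted delays
separated by exactly the merge radius can quantize to bin centers 0.16 ms
apart, which merges. The tests therefore probe the merge rule at generic
(non-bin-edge) delays.

## Spiking and bursting distributions

Interval statistics are summarized as complementary cumulative
distributions (CCDs), `P(value >= t)` on logarithmically spaced bins,
normalized to 1 at the smallest bin. Power-law behaviour is fitted as
`log10 P = alpha * log10 t + c` by least squares. Following the published
grid-search rule, both ends of the default fit window (0.01–1.0 s for
interspike intervals, with the probability window 1 down to 0.1) are
scaled over ±50% in 5% steps — a 21 × 21 grid read as multiplicative
scaling of each endpoint, which keeps the stated defaults at the grid
center — and the window with the highest Pearson R² wins; ties prefer the
widest window, then the smallest lower limit. With the grid width set to
zero the fit reduces exactly to the plain full-window regression (tested
to 1e-10). EC–DG feed-forward axon ISI distributions are non-linear in
the standard window and use a 0.1–0.2 s override.

Burst detection is not specified in the source analysis (it defers to
prior work), so we adopt the standard fixed-ISI-threshold definition:
maximal runs with every gap ≤ 100 ms and at least 3 spikes, both
configurable. These defaults sit comfortably around the 40–100 ms median
packet durations such cultures produce. From bursts we derive inter-burst
intervals (IBI), spikes per burst, burst duration (BD) and intraburst
spike rate (IBSR).

IBI CCDs show two regimes — fast "up-state" bursting at short intervals
and slow "down-state" bursting at long ones — and are fitted piecewise:
for each candidate crossover a fast segment is fitted below and a slow
segment above (each with the endpoint grid search, the crossover endpoint
pinned so the fast window's maximum equals the slow window's minimum),
the candidate maximizing summed R² wins, and the crossover is then
refined to the intersection point of the two fitted lines with iterated
refitting. The piecewise probability window spans two orders of
probability (1 down to 0.01), matching the range over which these
distributions are displayed; the extreme tail below that is few-sample
noise and is excluded.

BD and IBSR are log-normal; `fit_lognormal()` fits a Gaussian to the
probability density of the natural-log values (Freedman–Diaconis
histogram, nonlinear least squares seeded at the sample moments) and
reports the distribution median as `exp(m)` exactly.

Slope changes across conditions are reported as percent change of slope
*magnitude*, `100 (|alpha_cond| − |alpha_base|)/|alpha_base|`, so that a
shallower (less negative) slope is a negative "decrease", matching how
such changes are conventionally quoted; the feed-forward versus feedback
fraction `100 (|alpha_ff| − |alpha_fb|)/|alpha_fb|` follows the same
convention.

## Functional connectivity

Firing rates are binned at 100 ms. For every ordered (well electrode,
tunnel axon) combination in both orientations, a 10-s window slides in
100-ms steps; each window with at least four non-zero bins in each series
(the non-zero rule is read per series, config-exposed) contributes an
ordinary least-squares regression of target rate on source rate. Slopes
and Pearson R² are averaged over qualifying windows and the averaged
connection is kept as an edge when mean slope > 0.1 and mean R² > 0.2 —
the gates are applied to the averages, matching the published description
of plotting averaged weights; per-window gating is available via config
and can only reduce the edge count. Windows that would run past the end
of the recording are dropped rather than truncated, keeping window
variance constant. An edge's mean slope is its weight (below 1:
dampening; above 1: amplification), its mean R² its reliability.

The axon's rate series uses the spikes assigned to that axon, timed on
the more active of the tunnel's two electrodes (raw spike count), because
some electrodes couple weakly to the axon. Each edge inherits the axon's
transmission direction as its direction class. Edges connect wells to
tunnel axons only — no well–well or axon–axon edges.

A note on orientation: the window regression is symmetric in the two
series (the R² is identical and the reverse slope is `R²/slope`), so a
strong coupling is generally retained in both orientations. The
orientations are bookkeeping for the in/out metric split; recovery of
planted couplings is accordingly scored at the (well, axon) pair level in
the tests.

Graph metrics follow the published definitions: per node, direction class
and orientation, degrees (edge counts), slope centrality (sum of incident
mean slopes) and R² centrality (summed reliability), with per-region
means over well electrodes. Feed-forward/feedback balance is summarized
by Cohen's d with 95% CI per region × orientation × metric, and
reliability changes versus baseline are reported as mean ± SE of percent
change over per-tunnel, per-direction cells with a one-tailed t-test
against no change.

## Statistics

Slopes are compared by ANCOVA (homogeneity-of-slopes F test on the binned
log–log CCD points, unweighted by bin occupancy) with Tukey-adjusted
pairwise slope contrasts via estimated marginal trends; scalar group
comparisons use one-way ANOVA with Tukey's HSD, rejecting at p < 0.05.
Cohen's d uses the pooled SD with sign convention "first group minus
second"; its 95% CI defaults to the normal approximation (a noncentral-t
inversion is available), as the source analysis names neither method, and
bands follow 0.2/0.5/0.8 with 0.5–0.8 read as medium–strong. Effects are
meaningful when the CI excludes zero. Calibration tests hold the type-I
rate of the ANOVA and one-tailed t at 0.05 ± 0.01 over 2,000 null
replicates.

## The synthetic generator

Real recordings from this device are deposited in a public archive but
are not required: `generate_recording()` produces recordings with planted
ground truth emulating the statistical structure the analysis assumes.

* **Well activity.** By default each well electrode is a renewal train
  with bounded-Pareto ISIs — the CCD is exactly linear in log–log over
  the fit window, with per-region exponents (defaults around −1.2 to
  −1.4, the range such cultures display) on ISI bounds 0.01–10 s. The
  heavy tail produces packet-like clustering without an explicit burst
  model. An alternative `well_mode = "bursts"` uses `burst_process()`:
  two-regime exponential inter-burst gaps, log-normal burst durations
  (default median 50 ms) and log-normal intraburst rates.
* **Tunnel axons.** Each planted axon is a source process whose spikes
  appear on the upstream electrode and, shifted by the signed conduction
  delay plus Gaussian jitter, on the downstream electrode; each electrode
  independently misses a spike with the detection-failure probability,
  and each electrode adds Poisson background at the noise rate. This is
  the simplest process consistent with the paired-spike model.
* **Planted couplings.** A well→axon coupling makes the axon's 100-ms
  rate profile `slope × well rate + Gaussian noise`, realized as an
  inhomogeneous Poisson train (axon→well couplings are the mirror image).
  One driver per target: an axon or well follows at most one planted
  regressor.
* **Stimulation.** The 5-pulse and 40-pulse 100 Hz theta-patterned
  protocols are modelled purely as condition labels with modifiers:
  rates thinned, ISI exponents shallowed, and the planted couplings
  *sharpened* — the noisiest couplings (largest noise-to-slope ratio) are
  pruned first, survivors' noise shrinks and their slopes grow. The
  pruning-plus-potentiation reading reflects the selective-routing
  account of stimulation: fewer functional routes, each more reliable.
  Pulse-level stimulation is metadata, never simulated voltage.

Determinism: all randomness flows from `spec$seed` through R's global
RNG; the same spec yields byte-identical recordings.

What the generator does *not* emulate: refractory structure, waveform
shapes (sorting is upstream), spatial correlations between neighbouring
wells, non-stationary drift within a recording, and stimulus-evoked
transients. Passing tests therefore demonstrate correctness of the
inference machinery on data satisfying the stated statistical
assumptions, not robustness to every pathology of real cultures.

### Numerical choices in the test conditions

Distribution-recovery tests draw the quantities the fits operate on
directly from the planted samplers. Two construction details matter for
validity. First, a bounded sample's empirical CCD bends downward as it
approaches the upper bound (the subtracted tail mass), so the planted
upper bound is placed far above the fitted window (e.g. IBI samples on
[0.3, 5e4] s for a break at 2 s); otherwise the slow regime would be
unobservable within two orders of probability. Second, burst-count
recovery uses gap rates slow enough that the probability of an inter-burst
gap below the 100 ms detection threshold is small, since two bursts closer
than the threshold merge by definition.

Problem sizes follow the property statements: 20 planted tunnels at
300 s for direction recovery; 200 seeded 10 Hz Poisson tunnel pairs for
the chance control; 1e5 intervals for exponent recovery (±0.05); 30
planted couplings among 76 wells × 16 axons at 300 s for edge recovery
(precision and recall ≥ 0.9); 2,000 null replicates for calibration.

## Known limitations

* Tunnels with more than two electrodes, and waveform-shape clustering,
  are out of scope.
* The regression-based edge orientation cannot carry causal meaning; use
  the direction class (axonal conduction direction) for directionality.
* `fit_lognormal()` falls back to ln-sample moments if the Gaussian
  least-squares fit fails to converge; with fewer than ~10 values the fit
  is refused except in the exactly-degenerate case.
* The grid search optimizes R², which on noisy few-bin windows can prefer
  small windows; the tie-breaking rule (widest window first) and the
  probability-window filter mitigate but do not eliminate this.
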