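---
title: "HRV-driven declarative retrieval: model, parameters, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{HRV-driven declarative retrieval: model, parameters, and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette documents the scientific content of `hrvactr`: the retrieval
model and its assumptions, the physiological coupling, the parameters that
matter, what the synthetic-data generators do and do not emulate, and the
numerical and design decisions taken where the problem left room.

## The closed loop

A browsing session is a discrete-time loop at a 5 s tick. At each tick the
engine

1. looks up the activation-noise scale `s` from the most recent 3-beat HRV
   packet (sample-and-hold between packets),
2. retrieves the declarative chunk (product image) with maximal activation
   `A_i = B_i + S_i + eps_i`,
3. logs and *reinforces* the retrieved chunk — a presentation counts as a
   rehearsal and is appended to the chunk's occurrence history,
4. under the default `"chain"` context policy, installs the retrieved
   chunk's attributes as the next tick's spreading-activation sources.

Step 3 is what makes the system bistable: with low noise, the presented
chunk's base-level activation rises, which makes it win again, which
reinforces it again. That self-feeding loop is the computational analogue
of rumination, and modulating `s` is the only escape hatch. Whether the
physiological signal opens that hatch (counterbalance) or closes it when
the user is stressed (synchronize) is the scientific contrast the simulator
exists to study.

## Declarative memory

**Base level.** `B_i = ln(sum_j (t - t_j)^(-d)) + beta_i` over all
occurrence timestamps `t_j` of chunk `i` (absolute seconds: browsing visits
when the store is built, then presentation times as the session reinforces
chunks). Defaults `d = 0.05` and `beta_i = 0`. Note that `d = 0.05` is far
below the conventional ACT-R default of `0.5`: memories decay very slowly,
recency and frequency advantages persist, and looping is correspondingly
easy to enter. Both values are exposed (`memory_params(decay = )`,
per-chunk `offset`), but 0.05 is the regime this system is defined in.
Elapsed times are floored at `time_floor = 0.05` s so that a chunk
reinforced at the current instant has a large but finite trace
(`0.05^-0.05`, about +0.16 in log space) rather than an infinite one; the
floor only matters at the moment of presentation and any small positive
value behaves identically in practice.

**Spreading.** The fan equation
`S_i = sum_j (W/|C|) * max(mas - ln fan_j, 0)` over the context symbols
`j in C` that chunk `i` bears, with `W = 1` and `mas = 2` by default.
`fan_j` is the number of chunks bearing attribute `j`, so shared labels are
worth little and rare labels a lot. One deliberate departure from the
textbook form: association strengths are floored at zero. With the fans
that realistic stores produce (a time-period symbol can sit on a third of
all chunks, so `ln fan > mas`), the unfloored form turns a chunk's *own*
attributes into a net penalty once they become the context. The retrieved
chunk is then systematically disadvantaged at the next tick relative to a
neighbor that shares only its rare labels, and the zero-noise dynamics
settle into a two-chunk oscillation instead of single-chunk looping —
contradicting the degenerate-looping behavior the model is built around.
Flooring at zero restores the superset-dominance property (the chunk whose
attributes *are* the context always has maximal spreading) for every store
size, without retuning `mas` per dataset. Negative associations are not a
phenomenon this simulator needs; `mas` remains configurable for those who
want stronger fan discrimination.

**Noise.** `eps_i` is Gaussian with mean 0 and variance `(pi/3) s^2`. The
canonical ACT-R noise is logistic with variance `(pi^2/3) s^2`; that
variant is available via `memory_params(noise_dist = "logistic")`, but the
Gaussian form with the `pi/3` scaling is the default because it is the form
this system is specified with. At `s = 0` the noise is exactly zero (no
random numbers are consumed), which makes zero-noise sessions fully
deterministic and seed-independent. Retrieval has no threshold — the
simulated browser always shows something — and ties break toward the
lexicographically smallest image id for reproducibility.

## From heartbeats to `s`

The heart-rate monitor this models emits one packet per three beats, so
the stream is cut into non-overlapping 3-RRI windows:

1. `HRV = sqrt(sum (x - mean(x))^2 / 3)` — the *population* SD of the
   window. Two small readings of the definition were fixed once:
   the radical is applied (a standard deviation, not a mean square —
   `apply_sqrt = FALSE` restores the literal no-root variant), and the
   divisor is `n = 3` (`sd_type = "sample"` selects `n - 1`). With a
   3-sample window the choice only rescales by `sqrt(3/2)`, and since the
   baseline is processed identically the z-scores are nearly unaffected.
2. Counterbalance mode only: `HRV_inv = mu_b / HRV`, the reciprocal HRV
   rescaled by the raw baseline mean so it stays on the baseline's scale.
   A zero HRV (flat RRIs) is clamped at `1e-6` ms to keep the inversion
   finite; the resulting huge `HRV_inv` correctly maps "deeply stressed"
   to "very large noise".
3. `z = (value - mu_b) / sd_b` against the baseline window.
4. `s = max(z + 0.5, 0)`: at baseline-level arousal `s = 0.5`, mildly
   repetitive; half a standard deviation below baseline the noise is fully
   off.

**Baseline.** A relaxed pre-task recording supplies HRV packets 15–64
(1-based inclusive — 50 values; the first 14 are discarded as settling
time). Indices are configurable (`baseline_stats(indices = )`), and the
1-based inclusive reading was chosen as the natural one for an ordinal
range. In counterbalance mode the baseline values themselves are inverted
(using the raw mean) before `mu_b` and `sd_b` are computed — the most
literal reading of "the baseline is also inverted" — so task-time
`HRV_inv` values are standardized against the statistics of inverted
baseline values. The raw baseline mean is stored regardless because the
task-time inversion needs it. A constant baseline (zero SD) is an error,
not a silent degenerate standardization.

**Clocks.** Store occurrences are absolute (unix-like) seconds; the session
clock starts 1 s after the store's newest occurrence so history is
strictly in the past. HRV sample times are interpreted as seconds since
session start: the `s` in force at session time `tau` is that of the
latest packet with `time <= tau`, held constant between packets (no
interpolation — the physical device updates stepwise), with
`noise_s_default` (default 0.5, the baseline-level value) in force before
the first packet or when no stream is supplied.

## Digitizing visit times: X-means

Time-period attributes come from 1-D X-means on the pooled visit
timestamps: start with one cluster, repeatedly try to split a cluster in
two, accept the split when it improves the BIC of the clustering restricted
to that cluster (identical-variance spherical-Gaussian model, 2k free
parameters, mixture weights `n_c/n`), stop at `k_max = 8`. Two details:

* The 2-means step is solved exactly: in one dimension the optimal
  2-partition is a cut in sorted order, found by exhaustive threshold
  search with prefix sums. This is deterministic, never cuts inside a tie
  group, and avoids iterative-refinement edge cases on tiny clusters.
* Absolute timestamps are clustered (not hour-of-day): the generator and
  the intended logs have visit *sessions* (evenings, weekly episodes), and
  absolute-time clusters capture those directly. Greedy top-down splitting
  shares X-means' known blind spot — many equally spaced, equally sized
  groups can fail the first binary split even though the full k-way model
  has higher BIC — but session-structured timestamps are hierarchically
  separated (hours within days within weeks), which is exactly the regime
  greedy splitting handles well.

A record whose visits span several periods gets its modal period, ties
toward the earlier one. Cluster labels are ordered by center, so
`period_1` is always the earliest.

## Synthetic data

`gen_browsing_log()` emulates a few weeks of shopping-site browsing: 30
products, labels drawn with overlap from a 12-label pool (3 per product, so
fans realistically range from 1 to 10+), 2–12 visits per product scattered
(SD 30 min) around three weekly session centers. `gen_rri_stream()`
emulates the monitor: mean RRI 800 ms with 30 ms jitter plus a 20 ms,
10 s-period sinusoid (respiratory sinus arrhythmia) when relaxed; mean
700 ms, 5 ms jitter, no sinusoid when stressed. These defaults put the
relaxed/stressed windowed-HRV separation far above the stressed jitter
(a guard the test suite asserts), so downstream contrasts are not fixture
noise. What the generators do *not* emulate: LF/HF spectral structure,
ectopic beats and sensor artifacts, circadian drift, and any feedback from
the presented images to the user's physiology (the simulated "user" does
not react). Passing tests therefore demonstrate properties of the model
and pipeline — looping under low noise, mode contrast under stress — not
effects on people.

## Analysis harness

Sessions are summarized by total switches (adjacent ticks showing
different images) and unique images. Group comparisons use the Wilcoxon
rank-sum test with midranks; p-values are exact by full enumeration of all
`choose(n1+n2, n1)` labelings when `n1 + n2 <= 12` (924 splits at the
6 vs 6 study scale — exact inference is the point of a nonparametric test
at this size), and a tie-corrected normal approximation with continuity
correction above. Tests are two-sided by default and no multiple-testing
correction is applied at the study's `alpha = 0.10`; the report records
the level so readers can judge the uncorrected p-values themselves.
Spearman correlations are Pearson correlations of midranks and refuse
constant vectors rather than returning `NA` silently.

**Post-hoc power.** `posthoc_power()` uses the noncentral-t formulation
with the Wilcoxon–Mann–Whitney asymptotic-relative-efficiency correction:
both sample sizes are multiplied by the ARE before forming the
noncentrality parameter and degrees of freedom. The default parent
distribution is the conservative distribution-free minimum, ARE = 0.864
(the G*Power convention); normal (`3/pi`), logistic (`pi^2/9`) and Laplace
(`1.5`) parents and a plain t-test method are selectable. The min-ARE
default was chosen because it is the standard default of the software this
kind of analysis is routinely run in, and for the 6 vs 6, `d = 0.8`,
`alpha = 0.10` design it gives 0.325, in close agreement with the 0.318
this design is reported to have; the normal-parent ARE gives 0.351, which
is not. A Monte-Carlo cross-check in the test suite verifies that the
analytic value matches the rejection rate of the package's own exact test
on simulated normal shifts within 0.015.

## Problem sizes and runtime choices

The test and acceptance workloads are sized for a desk machine: 180-tick
(15 min) sessions, 30-chunk stores, 20-seed cohorts per mode,
`10^4`–`10^5` draws for Monte-Carlo oracles. These sizes give the
properties under test comfortable margins (e.g. the mode contrast in mean
switches is roughly 0.4 vs 172 switches per session, two orders of
magnitude above its sampling noise) while keeping the full suite in the
low minutes.

## Known limitations

* The association-strength formula and source weights of the original
  interactive system are not published; the fan equation with the
  zero floor documented above is this package's own choice.
* The simulated user has fixed physiology per scenario; claims about
  recovery, mood, or attention in humans are out of reach of this
  simulator by design.
* HRV is a 3-beat time-domain SD only; no artifact correction is applied,
  so real sensor data should be cleaned upstream.
* Exact rank-sum enumeration is quadratic-exponential in group size; above
  12 observations the normal approximation is used, which is standard but
  approximate.
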