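# hrvactr

Desk-scale simulation of a **biofeedback advertisement system**: an ACT-R
declarative-memory model chooses which product image (from the user's own
browsing history) to show every 5 seconds, while the model's retrieval-noise
parameter is driven in real time by the user's heart-rate variability (HRV).
Two couplings are available:

* **synchronize** — the noise scale *s* tracks HRV directly, so a stressed
  (low-HRV) user gets low-noise, highly repetitive retrieval: the model
  mirrors the user's arousal and can lock onto a few images the way
  rumination locks onto a few memories;
* **counterbalance** — *s* tracks the *inverse* of HRV (homeostatic
  regulation), so a stressed user instead receives diverse, distracting
  presentations.

The package is aimed at computational cognitive modeling and physiological
computing researchers who want to study this closed loop without hardware,
participants, or a browser: it ships seeded generators for multi-week
browsing logs and R-R interval (RRI) streams, the full model pipeline, and
the behavioral/statistical analysis harness used to compare the two modes.

## The model

Each product image is a declarative chunk *i* retrieved by activation

```
A_i = B_i + S_i + eps_i
```

* **Base level** `B_i = ln( sum_j (t - t_j)^(-d) ) + beta_i` over the
  chunk's occurrence times `t_j` (browsing visits and on-screen
  presentations), with decay `d = 0.05` and `beta_i = 0`. Frequent and
  recent exposure raises activation, which is what makes zero-noise
  retrieval collapse into a loop.
* **Spreading** `S_i = sum_j (W/|C|) * max(mas - ln fan_j, 0)` over context
  symbols `j` (the attributes of the previously shown image) that chunk *i*
  bears, where `fan_j` is how many chunks share attribute *j*. Attributes
  are the image's semantic labels plus a time-period symbol obtained by
  X-means clustering of its visit timestamps.
* **Noise** `eps_i ~ N(0, (pi/3) s^2)`, where *s* is set every three
  heartbeats from the RRI stream: HRV = population SD of the last three
  RRIs; counterbalance mode inserts `HRV_inv = mu_b / HRV`; the value is
  standardized against a relaxed baseline window (samples 15–64 of the
  baseline session) and mapped through `s = max(z + 0.5, 0)`.

Sessions run 900 s at a 5 s tick; every presented chunk is reinforced, so
the loop can feed itself. The analysis harness computes per-session switch
and unique-image counts, exact Wilcoxon rank-sum tests (full enumeration up
to 12 observations), Spearman correlations, and post-hoc power for the
Wilcoxon–Mann–Whitney design.

## Worked example

```r
library(hrvactr)

records <- gen_browsing_log(seed = 3)      # 30 products, 3 weekly periods
store   <- build_store(records, seed = 3)
glance(store)
#>   n_chunks n_attributes total_occurrences n_periods
#> 1       30           15               213         3

relaxed  <- gen_rri_stream("relaxed",  duration = 300, seed = 2)  # baseline
stressed <- gen_rri_stream("stressed", duration = 900, seed = 5)  # task

base_sync <- baseline_from_stream(relaxed, "sync")
base_coun <- baseline_from_stream(relaxed, "counterbalance")

log_sync <- run_session(store, process_stream(stressed, base_sync),
                        session_config(mode = "sync", seed = 7))
log_coun <- run_session(store, process_stream(stressed, base_coun),
                        session_config(mode = "counterbalance", seed = 7))
summarize_session(log_sync)
#>   total_switches unique_images mode  seed
#> 1              0             1 sync     7
summarize_session(log_coun)
#>   total_switches unique_images mode            seed
#> 1            172            27 counterbalance    7
```

The stressed stream has almost no RRI variability, so in sync mode every
z-score falls below −0.5, `s` clips to 0, and the session freezes on a
single image (0 switches). The counterbalance inversion maps the same
stream to large `s` (here 0.64–56.3), and the session switches images 172
times across 27 distinct products — the homeostatic mode breaks the loop.

The power routine reproduces the design-level sensitivity of a 6 vs 6
comparison at `alpha = 0.10`:

```r
posthoc_power(d = 0.8, n1 = 6, n2 = 6, alpha = 0.10)
#> [1] 0.3247915
```

`autoplot(log_coun)`, `plot_hrv_samples()`, and `plot_cohort()` visualize
logs, noise traces, and cohort comparisons. A command-line front end with
`gen-data`, `make-store`, `simulate`, and `analyze` subcommands is installed
at `system.file("scripts", "hrvactr", package = "hrvactr")`.

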