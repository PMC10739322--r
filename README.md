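# axotrace

Spike-train analysis for compartmentalized hippocampal cultures recorded
on multi-electrode arrays (MEAs) with microfluidic tunnels. The package is
written for experimenters who record the four sub-regions of the
trisynaptic loop — EC, DG, CA3, CA1 — in separate wells (19 electrodes
each) connected by axon-only tunnels, five per wall spanned by electrode
pairs 0.2 mm apart, and who want to answer three questions:

1. **Which axons cross each tunnel, and in which direction?**
   Spikes on the two tunnel electrodes are paired within the physiological
   conduction window (|Δt| in 0.2–1 ms over 0.2 mm). Tunnel validity is
   gated by the normalized matching index,
   `NMI = n_paired / max(n_up, n_down) > 0.2`. A histogram of signed
   delays is searched for peaks (count > mean + 1.9 SD, prominence ≥ 12%
   of the tallest bin, peaks within ±0.16 ms merged, fast peaks admitted
   down to 0.12 ms); each peak is one axon, and its delay sign gives the
   transmission direction — positive is feed-forward along
   EC > DG > CA3 > CA1 > EC, negative is feedback.

2. **How are spikes and bursts distributed?** Interval statistics are
   summarized as complementary cumulative distributions on log–log axes
   and fitted as `log10 P = α·log10 t + c`, with the fit window
   grid-searched (endpoints varied ±50% in 5% steps, highest R² wins;
   default window 0.01–1 s, probabilities 1 to 0.1). Inter-burst
   intervals get a piecewise two-slope fit (fast/slow bursting regimes
   with the crossover at the intersection of the fitted lines); burst
   durations and intraburst spike rates get log-normal fits in natural-log
   space with median `e^m`.

3. **Which wells talk to which axons?** Firing rates in 100 ms bins are
   regressed in 10-s sliding windows (100-ms steps, ≥ 4 non-zero bins per
   series); window-averaged regressions with mean slope > 0.1 and mean
   R² > 0.2 become directed, weighted edges between well electrodes and
   tunnel axons. Degrees, slope/R² centralities, feed-forward/feedback
   balance (Cohen's d with 95% CI) and reliability changes across
   stimulation conditions (no stimulation, 5-pulse HFS, 40-pulse HFS)
   summarize the network's routing.

A seeded synthetic-recording generator (`synth_spec()`,
`generate_recording()`, `simulate_experiment()`) plants ground-truth
axons, delays, distributions and well–axon couplings so that every stage
of the pipeline is verifiable without any external data.

## Worked example

Plant four axons with known delays and directions, generate a 5-minute
recording, and recover them:

```r
library(axotrace)

layout <- default_layout()   # 4 wells x 19 electrodes, 4 walls x 5 tunnels
axons <- tibble::tibble(tunnel_id = layout$tunnels$tunnel_id[1:4],
                        axon_index = 1L, delay_ms = c(0.5, -0.4, 0.7, -0.3),
                        spike_fraction = 1, source = NA_character_)
spec <- synth_spec(seed = 42, duration = 300, tunnel_axons = axons,
                   noise_rate = 0.8, detection_failure_p = 0.05,
                   delay_jitter_sd = 0.05)
sim <- generate_recording(spec, layout)
sim$recording
#> <mea_recording 'synthetic_seed42'> 610348 spikes / 84 electrodes; 300 s; condition no_stim

inference <- infer_axons(sim$recording, layout)
tidy(inference)
#> # A tibble: 4 × 7
#>   tunnel_id wall  axon_index peak_delay_ms direction    n_spikes peak_height
#>   <chr>     <chr>      <int>         <dbl> <chr>           <int>       <int>
#> 1 EC_DG_t1  EC_DG          1          0.5  feed_forward     2148         654
#> 2 EC_DG_t2  EC_DG          1         -0.38 feedback         2146         619
#> 3 EC_DG_t3  EC_DG          1          0.7  feed_forward     2101         662
#> 4 EC_DG_t4  EC_DG          1         -0.3  feedback         2068         651
```

All four planted axons come back with the right sign and a delay error
within one 0.04 ms histogram bin. The same recording's CA1 interspike
intervals recover the generator's power-law exponent (−1.25 for CA1):

```r
isis <- unlist(lapply(layout$wells$electrode_id[layout$wells$region == "CA1"],
                      \(el) diff(spike_train(sim$recording, el))))
glance(fit_power_law(compute_ccd(isis)))
#> # A tibble: 1 × 6
#>   alpha     c    r2  t_lo  t_hi n_bins
#>   <dbl> <dbl> <dbl> <dbl> <dbl>  <int>
#> 1 -1.25 -2.50 1.000 0.005   1.5     14
```

A full three-condition experiment — stimulation modelled as rate
thinning, slope shallowing and coupling sharpening — reproduces the
signature of network sharpening: fewer functional edges, higher edge
reliability, shallower ISI slopes:

```r
demo <- run_synthetic_demo(seed = 1)
demo$pipeline$summary[, c("condition", "n_edges", "mean_edge_r2",
                          "mean_well_isi_alpha")]
#> # A tibble: 3 × 4
#>   condition n_edges mean_edge_r2 mean_well_isi_alpha
#>   <chr>       <int>        <dbl>               <dbl>
#> 1 no_stim        24        0.614              -1.29
#> 2 hfs5           18        0.704              -0.981
#> 3 hfs40          12        0.751              -0.742
```

Each result type has `tidy()`/`glance()` methods, `autoplot()` methods
(delay histograms, CCD fits) and JSON serialization via
`write_results()`/`read_results()`.

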