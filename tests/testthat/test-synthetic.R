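test_that("generation is deterministic under a fixed seed and varies across seeds", {
  spec <- synth_spec(seed = 5, duration = 30, wells_per_region = 3)
  lay <- default_layout(3, 2)
  g1 <- generate_recording(spec, lay)
  g2 <- generate_recording(spec, lay)
  expect_equal(as.data.frame(g1$recording), as.data.frame(g2$recording))
  spec2 <- spec; spec2$seed <- 6
  g3 <- generate_recording(spec2, lay)
  expect_false(identical(g1$recording$time_s, g3$recording$time_s))
})

test_that("a noiseless axon is an exact delayed copy of its source", {
  lay <- default_layout(2, 1)
  ax <- tibble::tibble(tunnel_id = lay$tunnels$tunnel_id[1], axon_index = 1L,
                       delay_ms = 0.5, spike_fraction = 1,
                       source = NA_character_)
  spec <- synth_spec(seed = 8, duration = 60, wells_per_region = 2,
                     tunnel_axons = ax, noise_rate = 0,
                     detection_failure_p = 0, delay_jitter_sd = 0)
  g <- generate_recording(spec, lay)
  tun <- lay$tunnels[1, ]
  up <- spike_train(g$recording, tun$upstream_electrode)
  down <- spike_train(g$recording, tun$downstream_electrode)
  expect_equal(down, up + 5e-4)
})

test_that("bounded power-law samples match the closed-form CCD and exponent", {
  set.seed(11)
  v <- sample_bounded_pareto(1e5, -1.30, c(0.01, 10))
  expect_true(all(v >= 0.01 & v <= 10))
  # Kolmogorov-Smirnov distance against the analytic CCD
  tt <- exp(seq(log(0.01), log(10), length.out = 200))
  emp <- vapply(tt, function(ti) mean(v >= ti), numeric(1))
  expect_lt(max(abs(emp - pareto_ccd_exact(tt, -1.3, c(0.01, 10)))), 0.02)
  # full-range log-log regression recovers the exponent
  ccd <- compute_ccd(v, n_bins = 50)
  fit <- fit_power_law(ccd, fit_window = c(0.01, 10),
                       prob_window = c(0.001, 1), grid_max_frac = 0)
  expect_lt(abs(fit$alpha - (-1.30)), 0.05)
})

test_that("burst process plants log-normal durations with median exp(m)", {
  set.seed(12)
  bp <- burst_process(4500, rate_fast = 0.5, rate_slow = 0.05,
                      bd_ln_mean = log(0.05), bd_ln_sd = 0.5)
  expect_gt(nrow(bp$bursts), 500)
  fit <- fit_lognormal(bp$bursts$end_s - bp$bursts$start_s)
  expect_lt(abs(fit$median - 0.05) / 0.05, 0.05)
  # degenerate log-normal: vanishing ln-SD pins every burst at exp(m)
  set.seed(13)
  bp0 <- burst_process(50, bd_ln_sd = 1e-12)
  expect_equal(bp0$bursts$end_s - bp0$bursts$start_s,
               rep(0.05, nrow(bp0$bursts)), tolerance = 1e-6)
})

test_that("planted burst count matches the gap-process expectation", {
  set.seed(14)
  rate_fast <- 0.3; rate_slow <- 0.05; p_fast <- 0.7; dur <- 4000
  bp <- burst_process(dur, rate_fast, rate_slow, p_fast,
                      bd_ln_mean = log(0.05), bd_ln_sd = 0.3)
  mean_cycle <- p_fast / rate_fast + (1 - p_fast) / rate_slow +
    exp(log(0.05) + 0.3^2 / 2)
  expected <- dur / mean_cycle
  expect_lt(abs(nrow(bp$bursts) - expected) / expected,
            4 / sqrt(expected))  # within Poisson-scale error
  # detection recovers the planted count when gaps dwarf the ISI threshold
  b <- detect_bursts(bp$times, max_isi_s = 0.1, min_spikes = 3)
  expect_lt(abs(nrow(b) - nrow(bp$bursts)) / nrow(bp$bursts), 0.05)
})

test_that("stimulation modifiers thin rates and shallow exponents; unknown labels error", {
  spec <- synth_spec(seed = 15, duration = 120, wells_per_region = 4,
                     isi_exponent = c(EC = -1.3, DG = -1.3, CA3 = -1.3,
                                      CA1 = -1.3))
  same <- apply_stim_modifier(spec, "no_stim")
  expect_equal(same$isi_exponent, spec$isi_exponent)
  expect_equal(same$rate_factor, spec$rate_factor)

  mod <- spec
  mod$stim_modifiers$hfs5 <- list(rate_factor = 0.7, exponent_factor = 1,
                                  edge_keep_fraction = 1,
                                  edge_noise_factor = 1,
                                  edge_slope_factor = 1)
  lay <- default_layout(4, 1)
  base <- generate_recording(spec, lay)
  thinned <- generate_recording(apply_stim_modifier(mod, "hfs5"), lay)
  wells <- lay$wells$electrode_id
  n_base <- sum(base$recording$electrode_id %in% wells)
  n_thin <- sum(thinned$recording$electrode_id %in% wells)
  expect_lt(abs(n_thin / n_base - 0.7), 0.05)

  shallow <- apply_stim_modifier(spec, "hfs40")
  expect_true(all(abs(shallow$isi_exponent) < abs(spec$isi_exponent)))
  g40 <- generate_recording(shallow, lay)
  isis <- unlist(lapply(wells, function(el)
    diff(spike_train(g40$recording, el))))
  isis0 <- unlist(lapply(wells, function(el)
    diff(spike_train(base$recording, el))))
  f40 <- fit_power_law(compute_ccd(isis[isis > 0]))
  f0 <- fit_power_law(compute_ccd(isis0[isis0 > 0]))
  expect_lt(abs(f40$alpha), abs(f0$alpha))

  expect_error(apply_stim_modifier(spec, "hfs99"), "unknown condition")
})

test_that("sharpening modifiers prune the noisiest couplings and potentiate survivors", {
  planted <- tibble::tibble(
    well_electrode_id = paste0("EC_w", 1:4),
    tunnel_id = paste0("t", 1:4), axon_index = 1L,
    influence = "well_to_axon", slope = c(1, 1, 1, 1),
    noise_sd_hz = c(1, 8, 2, 9))
  spec <- synth_spec(seed = 1, planted_edges = planted)
  out <- apply_stim_modifier(spec, "hfs40")
  keep <- out$planted_edges
  expect_equal(nrow(keep), 2L)  # ceiling(0.45 * 4)
  expect_setequal(keep$tunnel_id, c("t1", "t3"))  # lowest relative noise
  expect_true(all(keep$slope > 1))
})
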