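test_that("an exact shifted copy pairs completely at the true delay", {
  set.seed(31)
  fx <- shifted_tunnel(n = 120, duration = 60, delay_ms = 0.5)
  pp <- match_spike_pairs(fx$up, fx$down)
  expect_equal(nrow(pp), length(fx$up))
  expect_lt(max(abs(pp$delay_ms - 0.5)), 1e-6)
  expect_false(is.unsorted(pp$up_time_s))
})

test_that("delays outside the magnitude window are never paired", {
  set.seed(32)
  up <- shifted_tunnel(n = 200, duration = 100)$up
  expect_equal(nrow(match_spike_pairs(up, up)), 0L)          # zero lag
  expect_equal(nrow(match_spike_pairs(up, up + 0.0015)), 0L) # too slow
  expect_equal(nrow(match_spike_pairs(numeric(0), up)), 0L)  # empty train
})

test_that("greedy pairing attains the exact maximum matching on sparse trains", {
  for (s in 1:5) {
    set.seed(100 + s)
    up <- sort(runif(rpois(1, 5 * 20), 0, 20))
    down <- sort(runif(rpois(1, 5 * 20), 0, 20))
    got <- nrow(match_spike_pairs(up, down))
    expect_equal(got, max_matching_oracle(up, down))
  }
})

test_that("NMI follows its definition and the strict 0.2 validity gate", {
  set.seed(33)
  fx <- shifted_tunnel(n = 100, duration = 50, delay_ms = 0.4)
  nmi <- compute_nmi(match_spike_pairs(fx$up, fx$down))
  expect_equal(nmi$nmi, 1.0)
  expect_true(nmi$valid)

  # 19 pairable of 100: below the gate; 30 of max(120, 100): above
  fake_pairs <- function(n_pairs, n_up, n_down) {
    up <- seq_len(n_up) * 0.1
    down <- c(up[seq_len(n_pairs)] + 5e-4,
              seq_len(n_down - n_pairs) * 0.1 + 1000)
    match_spike_pairs(up, sort(down))
  }
  low <- compute_nmi(fake_pairs(19, 100, 100))
  expect_equal(low$nmi, 0.19)
  expect_false(low$valid)
  ok <- compute_nmi(fake_pairs(30, 120, 100))
  expect_equal(ok$nmi, 0.25)
  expect_true(ok$valid)

  both_empty <- compute_nmi(match_spike_pairs(numeric(0), numeric(0)))
  expect_true(is.na(both_empty$nmi))
  expect_false(both_empty$valid)
  expect_match(both_empty$reason, "empty")
})

test_that("NMI is symmetric in the two electrode roles", {
  set.seed(34)
  up <- sort(runif(400, 0, 100))
  down <- sort(c(up[runif(400) < 0.6] + 4e-4, runif(150, 0, 100)))
  a <- compute_nmi(match_spike_pairs(up, down))
  b <- compute_nmi(match_spike_pairs(down, up))
  expect_equal(a$nmi, b$nmi)
})

test_that("delay histograms conserve counts and localize mass", {
  set.seed(35)
  fx <- shifted_tunnel(n = 120, duration = 60, delay_ms = 0.5)
  pp <- match_spike_pairs(fx$up, fx$down)
  h <- build_delay_histogram(pp, bin_width_ms = 0.04)
  expect_equal(sum(h$counts), nrow(pp))
  expect_equal(sum(h$counts > 0), 1L)

  # two point masses 60/40
  up <- seq(0.5, 100, by = 0.5)
  n <- length(up)
  down <- up + ifelse(seq_len(n) %% 5 < 3, 5e-4, -5e-4)
  pp2 <- match_spike_pairs(up, sort(down))
  h2 <- build_delay_histogram(pp2)
  nz <- which(h2$counts > 0)
  expect_equal(length(nz), 2L)
  expect_equal(sort(h2$counts[nz] / n), c(0.4, 0.6))

  # jittered delays: histogram mean matches the sample mean
  set.seed(36)
  fx3 <- shifted_tunnel(n = 3000, duration = 600, delay_ms = 0.5)
  down3 <- sort(fx3$up + 5e-4 + rnorm(length(fx3$up), 0, 5e-5))
  pp3 <- match_spike_pairs(fx3$up, down3)
  h3 <- build_delay_histogram(pp3)
  hist_mean <- sum(h3$bin_centers_ms * h3$counts) / sum(h3$counts)
  expect_lt(abs(hist_mean - mean(pp3$delay_ms)), 0.02)
  expect_lt(abs(hist_mean - 0.5), 0.02)

  expect_error(build_delay_histogram(match_spike_pairs(numeric(0),
                                                       numeric(0))),
               "no pairable activity")
})

test_that("peak detection matches the exhaustive oracle across merge separations", {
  base_sep <- c(0.08, 0.12, 0.16, 0.20, 0.28, 0.40)
  for (sep in base_sep) {
    for (s in 1:3) {
      set.seed(1000 * s + round(sep * 100))
      base <- sort(runif(2500, 0, 300))
      base <- base[c(TRUE, diff(base) > 0.004)]
      a1 <- base[seq(1, length(base), by = 2)]
      a2 <- base[seq(2, length(base), by = 2)]
      up <- sort(c(a1, a2))
      down <- sort(c(a1 + 4.1e-4, a2 + (0.41 + sep) / 1000))
      pp <- match_spike_pairs(up, down)
      h <- build_delay_histogram(pp)
      ax <- detect_axon_peaks(h, pp)
      oracle <- peak_oracle(h$counts, h$bin_centers_ms)
      expect_equal(sort(ax$peak_delay_ms), oracle)
      expect_equal(nrow(ax), if (sep > 0.16) 2L else 1L)
    }
  }
})

test_that("opposite-sign peaks give two axons with opposite directions", {
  set.seed(37)
  base <- sort(runif(2400, 0, 300))
  base <- base[c(TRUE, diff(base) > 0.004)]
  a1 <- base[seq(1, length(base), by = 2)]
  a2 <- base[seq(2, length(base), by = 2)]
  up <- sort(c(a1, a2))
  down <- sort(c(a1 + 5e-4, a2 - 4e-4))
  pp <- match_spike_pairs(up, down)
  ax <- detect_axon_peaks(build_delay_histogram(pp), pp)
  expect_equal(nrow(ax), 2L)
  expect_setequal(ax$direction, c("feed_forward", "feedback"))
  expect_equal(ax$direction[ax$peak_delay_ms > 0], "feed_forward")

  # spike trains partition the pairs disjointly
  trains <- axon_spike_trains(ax, pp)
  expect_equal(sum(lengths(trains)), sum(ax$n_spikes))
  expect_equal(length(intersect(trains[[1]], trains[[2]])), 0L)
  expect_false(any(vapply(trains, is.unsorted, logical(1))))
})

test_that("pair assignment tracks the generating axon under jitter", {
  lay <- default_layout(2, 1)
  tun_id <- lay$tunnels$tunnel_id[1]
  ax <- tibble::tibble(tunnel_id = tun_id, axon_index = 1:2,
                       delay_ms = c(0.5, -0.4),
                       spike_fraction = 1, source = NA_character_)
  spec <- synth_spec(seed = 38, duration = 300, wells_per_region = 2,
                     tunnel_axons = ax, noise_rate = 0.5,
                     detection_failure_p = 0.02, delay_jitter_sd = 0.05)
  g <- generate_recording(spec, lay)
  inf <- infer_axons(g$recording, lay)
  expect_equal(nrow(inf$axons), 2L)
  truth <- g$truth$axons
  correct <- 0; total <- 0
  for (k in seq_len(nrow(inf$axons))) {
    est <- inf$axons[k, ]
    true_row <- truth[which.min(abs(truth$delay_ms - est$peak_delay_ms)), ]
    train <- inf$trains[[paste0(tun_id, "#", est$axon_index)]]
    events <- true_row$events[[1]]
    hits <- sum(vapply(train, function(t)
      any(abs(events - t) < 2e-4), logical(1)))
    correct <- correct + hits; total <- total + length(train)
  }
  expect_gt(correct / total, 0.95)
})

test_that("sub-window peaks are admitted only with the fast-conduction flag", {
  set.seed(39)
  fx <- shifted_tunnel(n = 2000, duration = 300, delay_ms = 0.15)
  pp <- match_spike_pairs(fx$up, fx$down, window_ms = c(0.12, 1.0))
  h <- build_delay_histogram(pp)
  with_flag <- detect_axon_peaks(h, pp, admit_fast = TRUE)
  expect_equal(nrow(with_flag), 1L)
  expect_lt(abs(with_flag$peak_delay_ms - 0.15), 0.04)
  without <- detect_axon_peaks(h, pp, admit_fast = FALSE)
  expect_equal(nrow(without), 0L)
})
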