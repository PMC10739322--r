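test_that("burst detection follows the fixed-ISI-threshold definition", {
  t1 <- c(seq(0, 0.09, by = 0.01), seq(5.2, 5.29, by = 0.01))
  b <- detect_bursts(t1, max_isi_s = 0.1, min_spikes = 3)
  expect_equal(nrow(b), 2L)
  expect_equal(b$n_spikes, c(10L, 10L))
  expect_equal(b$start_s, c(0, 5.2))

  expect_equal(nrow(detect_bursts(seq(0, 60, by = 1), 0.1, 3)), 0L)
  expect_equal(nrow(detect_bursts(numeric(0))), 0L)

  # idempotent re-detection and invariance to silence outside bursts
  b2 <- detect_bursts(c(t1, 100, 210), 0.1, 3)
  expect_equal(b2, b)
})

test_that("interval and burst-statistic series match hand computation", {
  expect_equal(interval_series(c(0, 0.1, 0.3), "isi"), c(0.1, 0.2))
  expect_equal(interval_series(0.5, "isi"), numeric(0))
  bursts <- tibble::tibble(start_s = c(0, 1.0), end_s = c(0.05, 1.06),
                           n_spikes = c(5L, 8L),
                           bd_s = c(0.05, 0.06), ibsr = c(100, 8 / 0.06))
  expect_equal(interval_series(bursts, "ibi"), 0.95)
  expect_equal(interval_series(bursts, "spb"), c(5, 8))
  expect_equal(interval_series(bursts, "bd"), c(0.05, 0.06))
  expect_equal(interval_series(bursts[1, ], "ibi"), numeric(0))
})

test_that("CCDs are normalized, non-increasing, and match the analytic curve", {
  cc <- compute_ccd(rep(0.1, 500), n_bins = 10)
  expect_equal(cc$p[1], 1)
  expect_true(all(cc$p[cc$t <= 0.1] == 1))

  set.seed(41)
  v <- sample_bounded_pareto(1e5, -1.1, c(0.02, 5))
  cc2 <- compute_ccd(v, 60)
  expect_true(all(diff(cc2$p) <= 0))
  expect_lt(max(abs(cc2$p - pareto_ccd_exact(cc2$t, -1.1, c(0.02, 5)))),
            0.02)
  expect_error(compute_ccd(numeric(0)), "no values")
  expect_error(compute_ccd(c(1, -1)), "values > 0")
})

test_that("an exact power-law CCD is fitted perfectly in every window", {
  t <- 10^seq(-2, 0, length.out = 40)
  ccd <- structure(tibble::tibble(t = t, p = (t / t[1])^-1.2 * 1),
                  class = c("ccd", "tbl_df", "tbl", "data.frame"))
  ccd$p <- ccd$p / ccd$p[1]
  fit <- fit_power_law(ccd, prob_window = c(0, 1))
  expect_equal(fit$alpha, -1.2, tolerance = 1e-10)
  expect_equal(fit$r2, 1, tolerance = 1e-10)
})

test_that("a zero-width grid equals the plain full-window regression", {
  set.seed(42)
  v <- sample_bounded_pareto(2e4, -1.3, c(0.01, 10))
  ccd <- compute_ccd(v, 50)
  fit <- fit_power_law(ccd, fit_window = c(0.01, 1), grid_max_frac = 0)
  keep <- ccd$p > 0 & ccd$p >= 0.1 & ccd$t >= 0.01 & ccd$t <= 1
  oracle <- stats::lm(log10(p) ~ log10(t), data = ccd[keep, ])
  expect_lt(abs(fit$alpha - unname(coef(oracle)[2])), 1e-10)
  expect_lt(abs(fit$c - unname(coef(oracle)[1])), 1e-10)
  expect_lt(abs(fit$r2 - summary(oracle)$r.squared), 1e-10)
})

test_that("grid-searched fits recover planted exponents within 0.05", {
  for (alpha in c(-0.8, -1.2, -1.6)) {
    set.seed(43 + round(10 * alpha))
    v <- sample_bounded_pareto(1e5, alpha, c(0.01, 10))
    fit <- fit_power_law(compute_ccd(v, 50))
    expect_lt(abs(fit$alpha - alpha), 0.05)
  }
})

test_that("a configured fit-window override is honored", {
  set.seed(44)
  v <- sample_bounded_pareto(5e4, -1.2, c(0.01, 10))
  fit <- fit_power_law(compute_ccd(v, 60), fit_window = c(0.1, 0.2),
                       prob_window = c(0.001, 1), grid_max_frac = 0)
  expect_gte(fit$fit_window[1], 0.1 - 1e-12)
  expect_lte(fit$fit_window[2], 0.2 + 1e-12)
  expect_lt(abs(fit$alpha - (-1.2)), 0.1)
})

test_that("piecewise fits recover two-regime structure and degenerate to one slope", {
  set.seed(45)
  ib <- sample_piecewise_pareto(20000, -1.5, -0.4, 2, c(0.3, 5e4))
  pf <- fit_piecewise_ibi(compute_ccd(ib, 60))
  expect_lt(abs(pf$crossover - 2) / 2, 0.2)
  expect_lt(abs(pf$fast$alpha - (-1.5)), 0.1)
  expect_lt(abs(pf$slow$alpha - (-0.4)), 0.1)
  expect_equal(pf$fast$fit_window[2], pf$slow$fit_window[1])

  set.seed(46)
  v <- sample_bounded_pareto(5e4, -1.0, c(0.1, 1e4))
  pf1 <- fit_piecewise_ibi(compute_ccd(v, 60))
  expect_lt(abs(pf1$fast$alpha - pf1$slow$alpha), 0.05)
})

test_that("a generator crossover shift from 5 s to 1 s is detected", {
  set.seed(47)
  pre <- fit_piecewise_ibi(compute_ccd(
    sample_piecewise_pareto(20000, -1.5, -0.4, 5, c(0.5, 1e5)), 60))
  post <- fit_piecewise_ibi(compute_ccd(
    sample_piecewise_pareto(20000, -1.5, -0.4, 1, c(0.2, 3e4)), 60))
  expect_lt(abs(pre$crossover - 5) / 5, 0.25)
  expect_lt(abs(post$crossover - 1) / 1, 0.25)
  expect_lt(post$crossover, pre$crossover)
})

test_that("log-normal fits return exp(m) as the median", {
  fit0 <- fit_lognormal(rep(0.05, 25))
  expect_equal(fit0$m, log(0.05))
  expect_equal(fit0$median, 0.05)
  expect_equal(fit0$s, 0)

  set.seed(48)
  v <- rlnorm(1e4, log(0.05), 0.5)
  fit <- fit_lognormal(v)
  expect_lt(abs(fit$median - 0.05) / 0.05, 0.05)
  # ln-sample-moment oracle
  expect_lt(abs(fit$m - mean(log(v))), 0.05)
  expect_equal(fit$median, exp(fit$m))
  expect_error(fit_lognormal(c(1, 0)), "positive")
})

test_that("slope comparisons use magnitude changes against the baseline", {
  fits <- tibble::tibble(
    group = rep(c("EC", "EC", "DG", "DG"), 2),
    direction = rep(c("feed_forward", "feedback"), 4),
    condition = rep(c("no_stim", "hfs5"), each = 4),
    alpha = c(-1.0, -1.0, -1.2, -1.0, -0.8, -1.0, -1.2, -1.0))
  cmp <- compare_slopes(fits)
  d <- cmp$delta
  # identical fits give zero change
  expect_equal(d$delta_percent[d$condition == "no_stim"], rep(0, 4))
  # -1.0 -> -0.8 is a 20% decrease in slope magnitude (shallower)
  ec_ff <- d$delta_percent[d$group == "EC" & d$condition == "hfs5" &
                             d$direction == "feed_forward"]
  expect_equal(ec_ff, -20)
  # feed-forward -1.2 vs feedback -1.0: +20% excess feed-forward
  ff <- cmp$ff_fb
  expect_equal(ff$ff_fb_fraction[ff$group == "DG" &
                                   ff$condition == "no_stim"], 20)
  expect_error(compare_slopes(dplyr::filter(fits, condition == "hfs5")),
               "baseline")
})
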