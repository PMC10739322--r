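test_that("rate binning conserves spike counts", {
  r <- bin_rates(seq(0.05, 0.95, by = 0.1), 0.1, 1)
  expect_equal(r$rate, rep(10, 10))
  expect_equal(bin_rates(numeric(0), 0.1, 2)$rate, rep(0, 20))
  set.seed(51)
  times <- sort(runif(500, 0, 60))
  r2 <- bin_rates(times, 0.1, 60)
  expect_equal(sum(r2$rate) * 0.1, sum(times < 60))
})

test_that("windowed regressions recover identity and planted couplings, and reject noise", {
  set.seed(52)
  x <- bin_rates(sort(runif(3000, 0, 300)), 0.1, 300)
  wr <- windowed_regressions(x, x)
  expect_equal(nrow(wr), 3000 - 100 + 1)
  q <- wr$qualifies
  expect_true(all(abs(wr$slope[q] - 1) < 1e-9))
  expect_true(all(abs(wr$r2[q] - 1) < 1e-9))

  # slope 1.5 coupling: window-mean slope matches the full-series oracle
  set.seed(53)
  xr <- rpois(3000, 2) / 0.1
  yr <- 1.5 * xr + rnorm(3000, 0, 5)
  wr2 <- windowed_regressions(xr, yr)
  full <- unname(coef(lm(yr ~ xr))[2])
  expect_lt(abs(mean(wr2$slope[wr2$qualifies]) - full), 0.1)
  expect_lt(abs(full - 1.5), 0.05)

  # independent series stay below the reliability gate
  below <- vapply(1:20, function(s) {
    set.seed(600 + s)
    a <- rpois(1200, 1) / 0.1
    b <- rpois(1200, 1) / 0.1
    w <- windowed_regressions(a, b)
    mean(w$r2[w$qualifies]) < 0.2
  }, logical(1))
  expect_gte(mean(below), 0.95)

  expect_error(windowed_regressions(xr, yr[-1]), "lengths")
})

test_that("edge gates drop weak couplings and keep dampening ones", {
  lay <- default_layout(4, 1)
  tun <- lay$tunnels$tunnel_id[1:2]
  ax <- tibble::tibble(tunnel_id = tun, axon_index = 1L,
                       delay_ms = c(0.5, -0.4), spike_fraction = 1,
                       source = NA_character_)
  planted <- tibble::tibble(
    well_electrode_id = c("EC_w01", "DG_w01"),
    tunnel_id = tun, axon_index = 1L, influence = "well_to_axon",
    slope = c(0.05, 0.5), noise_sd_hz = c(0.5, 2))
  spec <- synth_spec(seed = 54, duration = 300, wells_per_region = 4,
                     tunnel_axons = ax, planted_edges = planted)
  g <- generate_recording(spec, lay)
  inf <- infer_axons(g$recording, lay)
  ed <- build_edges(g$recording, lay, inf)
  has_edge <- function(well, tid) {
    any((ed$source == well | ed$target == well) & ed$tunnel_id == tid)
  }
  expect_false(has_edge("EC_w01", tun[1]))  # slope below the 0.1 gate
  expect_true(has_edge("DG_w01", tun[2]))   # dampening slope retained
  damp <- ed[(ed$source == "DG_w01" | ed$target == "DG_w01") &
               ed$orientation == "well_to_axon", ]
  expect_lt(damp$mean_slope, 1)
  expect_gt(damp$mean_slope, 0.1)
  # direction class inherited from the axon
  expect_equal(unique(ed$direction_class[ed$tunnel_id == tun[2]]),
               "feedback")
})

test_that("graph metrics match hand enumeration on a five-edge fixture", {
  edges <- tibble::tibble(
    source = c("w1", "w1", "w2", "t1#1", "t2#1"),
    target = c("t1#1", "t2#1", "t1#1", "w3", "w1"),
    orientation = c("well_to_axon", "well_to_axon", "well_to_axon",
                    "axon_to_well", "axon_to_well"),
    tunnel_id = c("t1", "t2", "t1", "t1", "t2"),
    axon_index = 1L,
    direction_class = c("feed_forward", "feedback", "feed_forward",
                        "feed_forward", "feedback"),
    mean_slope = c(1.5, 0.8, 0.6, 1.2, 0.9),
    mean_r2 = c(0.9, 0.5, 0.4, 0.7, 0.6),
    n_windows = 10L)
  gm <- graph_metrics(edges)
  n <- gm$nodes
  pick <- function(node, cls) n[n$node == node & n$direction_class == cls, ]
  w1_ff <- pick("w1", "feed_forward")
  expect_equal(w1_ff$degree_out, 1L)
  expect_equal(w1_ff$degree_in, 0L)
  expect_equal(w1_ff$slope_centrality_out, 1.5)
  w1_fb <- pick("w1", "feedback")
  expect_equal(w1_fb$degree_out, 1L)
  expect_equal(w1_fb$degree_in, 1L)
  expect_equal(w1_fb$r2_centrality_in, 0.6)
  t1_ff <- pick("t1#1", "feed_forward")
  expect_equal(t1_ff$degree_in, 2L)
  expect_equal(t1_ff$degree_out, 1L)
  expect_equal(t1_ff$slope_centrality_in, 1.5 + 0.6)
  expect_equal(t1_ff$r2_centrality_out, 0.7)

  # handshake identity per direction class
  hs <- n |>
    dplyr::group_by(direction_class) |>
    dplyr::summarise(din = sum(degree_in), dout = sum(degree_out))
  counts <- table(edges$direction_class)
  expect_equal(hs$din, as.integer(counts[hs$direction_class]))
  expect_equal(hs$dout, as.integer(counts[hs$direction_class]))

  # empty edge set gives all-zero metrics
  gm0 <- graph_metrics(empty <- edges[0, ], layout = default_layout(2, 1))
  expect_true(all(gm0$nodes$degree_in == 0))
  expect_true(all(gm0$nodes$degree_out == 0))
})

test_that("balance summaries contrast feed-forward and feedback per region", {
  lay <- default_layout(6, 1)
  mk_edges <- function(ff_extra) {
    wells <- lay$wells$electrode_id[lay$wells$region == "EC"]
    base <- tibble::tibble(
      source = wells, target = "EC_DG_t1#1",
      orientation = "well_to_axon", tunnel_id = "EC_DG_t1",
      axon_index = 1L, direction_class = "feedback",
      mean_slope = 0.8, mean_r2 = 0.5, n_windows = 5L)
    if (ff_extra) {
      base <- dplyr::bind_rows(base, dplyr::mutate(
        base, direction_class = "feed_forward", mean_r2 = 0.8,
        target = "DG_CA3_t1#1", tunnel_id = "DG_CA3_t1"))
    }
    base
  }
  balanced <- mk_edges(TRUE)
  gm <- graph_metrics(balanced, lay)
  gm2 <- graph_metrics(mk_edges(TRUE), lay)
  bs <- balance_summary(list(no_stim = gm, hfs40 = gm2),
                        list(no_stim = balanced, hfs40 = mk_edges(TRUE)))
  # identical ff/fb degree profiles inside EC give a zero effect size
  ec_deg <- bs$effects[bs$effects$region == "EC" &
                         bs$effects$metric == "degree" &
                         bs$effects$orientation == "out", ]
  expect_equal(ec_deg$d, rep(0, nrow(ec_deg)))
  # reliability table carries both classes
  rel <- bs$reliability
  expect_setequal(unique(rel$direction_class),
                  c("feed_forward", "feedback"))
  expect_error(balance_summary(list(a = gm), list(a = balanced)),
               "2 conditions")
})
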