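# Independent oracles and small fixture builders used across tests.

# closed-form CCD of the bounded power-law distribution
pareto_ccd_exact <- function(t, alpha, range) {
  lo_a <- range[1]^alpha
  hi_a <- range[2]^alpha
  pmin(1, pmax(0, (t^alpha - hi_a) / (lo_a - hi_a)))
}

# maximum-cardinality one-to-one pairing oracle on the candidate graph,
# solved exactly as a bipartite matching (independent of the greedy path)
max_matching_oracle <- function(up, down, window_ms = c(0.2, 1)) {
  w_lo <- window_ms[1] / 1000
  w_hi <- window_ms[2] / 1000
  cand <- which(outer(down, up, function(d, u) {
    ad <- abs(d - u)
    ad >= w_lo & ad <= w_hi
  }), arr.ind = TRUE)
  if (!nrow(cand)) return(0L)
  g <- igraph::make_bipartite_graph(
    types = c(rep(FALSE, length(up)), rep(TRUE, length(down))),
    edges = as.vector(t(cbind(cand[, "col"], length(up) + cand[, "row"]))))
  igraph::max_bipartite_match(g)$matching_size
}

# exhaustive peak-finding oracle on binned counts: every local maximum is
# tested against the count and prominence gates (zero-padded ends), then
# peaks are merged by taller-first greedy exclusion within the radius
peak_oracle <- function(counts, centers, sd_threshold = 1.9,
                        prominence_frac = 0.12, merge_radius = 0.16,
                        floor_ms = 0.12) {
  n <- length(counts)
  padded <- c(0, counts, 0)
  is_max <- vapply(seq_len(n), function(i) {
    left <- padded[i]; right <- padded[i + 2]
    # plateau handling: strictly above the previous distinct value and at
    # least the next
    counts[i] > 0 && counts[i] > left && counts[i] > right
  }, logical(1))
  cand <- which(is_max)
  prom <- vapply(cand, function(i) {
    h <- counts[i]
    base_l <- if (i > 1) {
      lowest <- Inf
      found <- NA
      for (j in rev(seq_len(i - 1))) {
        if (counts[j] > h) { found <- lowest; break }
        lowest <- min(lowest, counts[j])
      }
      if (is.na(found)) min(lowest, 0) else found
    } else 0
    base_r <- if (i < n) {
      lowest <- Inf
      found <- NA
      for (j in (i + 1):n) {
        if (counts[j] > h) { found <- lowest; break }
        lowest <- min(lowest, counts[j])
      }
      if (is.na(found)) min(lowest, 0) else found
    } else 0
    h - max(base_l, base_r)
  }, numeric(1))
  gate <- mean(counts) + sd_threshold * stats::sd(counts)
  keep <- counts[cand] > gate & prom >= prominence_frac * max(counts) &
    abs(centers[cand]) >= floor_ms
  cand <- cand[keep]
  accepted <- integer(0)
  for (i in cand[order(-counts[cand], abs(centers[cand]))]) {
    if (!length(accepted) ||
        all(abs(centers[i] - centers[accepted]) > merge_radius + 1e-9)) {
      accepted <- c(accepted, i)
    }
  }
  sort(centers[accepted])
}

# spike-pair fixture: a base train with enforced minimum ISI plus an exact
# downstream copy at a given delay (ms)
shifted_tunnel <- function(n = 500, duration = 300, delay_ms = 0.5,
                           min_isi = 0.003) {
  up <- sort(stats::runif(n, 0, duration))
  up <- up[c(TRUE, diff(up) > min_isi)]
  list(up = up, down = sort(up + delay_ms / 1000))
}

expect_tibble <- function(x) {
  expect_s3_class(x, "tbl_df")
}
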