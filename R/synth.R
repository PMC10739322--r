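#' Bounded power-law (Pareto) interval sampler
#'
#' Draws intervals whose complementary cumulative distribution (CCD) is
#' `P(T >= t) = (t^alpha - hi^alpha) / (lo^alpha - hi^alpha)` on
#' `[lo, hi]`, i.e. a straight line of slope `alpha` on log-log axes for
#' `t` well below the upper bound. Sampling is by inversion, so a fixed RNG
#' state gives a fixed sample.
#'
#' @param n Number of draws.
#' @param alpha CCD slope (negative, dimensionless).
#' @param range `c(lo, hi)` bounds in the value's units, `lo > 0`.
#' @return Numeric vector of length `n`.
#' @export
sample_bounded_pareto <- function(n, alpha, range) {
  stopifnot(alpha < 0, range[1] > 0, range[2] > range[1])
  u <- stats::runif(n)
  lo_a <- range[1]^alpha
  hi_a <- range[2]^alpha
  (u * (lo_a - hi_a) + hi_a)^(1 / alpha)
}

#' Two-regime bounded power-law interval sampler
#'
#' Intervals whose CCD follows slope `alpha_fast` below `crossover` and
#' `alpha_slow` above it (continuous at the crossover), truncated to
#' `range`. Used to emulate the fast ("up state") and slow ("down state")
#' bursting regimes of inter-burst interval distributions.
#'
#' @inheritParams sample_bounded_pareto
#' @param alpha_fast,alpha_slow CCD slopes below/above the crossover
#'   (negative).
#' @param crossover Regime boundary, same units as `range`.
#' @export
sample_piecewise_pareto <- function(n, alpha_fast, alpha_slow, crossover,
                                    range) {
  stopifnot(alpha_fast < 0, alpha_slow < 0,
            range[1] > 0, crossover > range[1], crossover < range[2])
  lo <- range[1]; hi <- range[2]
  s_break <- (crossover / lo)^alpha_fast
  s_hi <- s_break * (hi / crossover)^alpha_slow
  # draw survival level uniformly on (s_hi, 1] and invert piecewise
  u <- stats::runif(n, min = s_hi, max = 1)
  fast <- u >= s_break
  out <- numeric(n)
  out[fast] <- lo * u[fast]^(1 / alpha_fast)
  out[!fast] <- crossover * (u[!fast] / s_break)^(1 / alpha_slow)
  out
}

#' Renewal spike train with bounded power-law ISIs
#'
#' @param duration Train length in seconds.
#' @param alpha ISI CCD slope (negative).
#' @param isi_range `c(lo, hi)` ISI bounds in seconds.
#' @param thin Keep each spike independently with this probability
#'   (rate modifier; 1 = keep all).
#' @return Strictly ascending spike times in `[0, duration]`.
#' @export
powerlaw_train <- function(duration, alpha, isi_range, thin = 1) {
  mean_isi <- bounded_pareto_mean(alpha, isi_range)
  times <- numeric(0)
  t_last <- stats::runif(1, 0, mean_isi)
  repeat {
    n_draw <- max(100L, ceiling(1.3 * (duration - t_last) / mean_isi))
    isis <- sample_bounded_pareto(n_draw, alpha, isi_range)
    new <- t_last + cumsum(isis)
    times <- c(times, new)
    t_last <- new[length(new)]
    if (t_last > duration) break
  }
  times <- times[times <= duration]
  if (thin < 1) times <- times[stats::runif(length(times)) < thin]
  times
}

bounded_pareto_mean <- function(alpha, range) {
  a <- -alpha
  lo <- range[1]; hi <- range[2]
  if (abs(a - 1) < 1e-9) {
    m <- (log(hi) - log(lo)) * lo / (1 - (lo / hi))
  } else {
    norm <- lo^-a - hi^-a
    m <- (a / (a - 1)) * (lo^(1 - a) - hi^(1 - a)) / norm
  }
  m
}

#' Bursty spike train with log-normal burst durations and rates
#'
#' Generates spikes grouped into bursts ("packets"): inter-burst gaps come
#' from a two-regime exponential mixture (fast/slow bursting states), burst
#' durations (BD) are log-normal with ln-mean `bd_ln_mean` and ln-SD
#' `bd_ln_sd`, and intraburst spike rates (IBSR) are log-normal in
#' spikes/s. The spike count of each burst is `max(min_spikes,
#' round(IBSR * BD))`; the first and last spike pin the burst ends so the
#' realized duration equals the drawn one.
#'
#' @param duration Train length in seconds.
#' @param rate_fast,rate_slow Gap rates (events/s) of the fast and slow
#'   regimes; gaps are `Exp(rate_fast)` with probability `p_fast`, else
#'   `Exp(rate_slow)`.
#' @param p_fast Mixture weight of the fast regime.
#' @param bd_ln_mean,bd_ln_sd Log-normal burst-duration parameters
#'   (ln-seconds).
#' @param ibsr_ln_mean,ibsr_ln_sd Log-normal intraburst-spike-rate
#'   parameters (ln(spikes/s)).
#' @param min_spikes Minimum spikes per burst.
#' @return List with `times` (spike times, s) and `bursts` (tibble of
#'   planted `start_s`, `end_s`, `n_spikes`).
#' @export
burst_process <- function(duration, rate_fast = 1, rate_slow = 0.1,
                          p_fast = 0.7,
                          bd_ln_mean = log(0.05), bd_ln_sd = 0.5,
                          ibsr_ln_mean = log(150), ibsr_ln_sd = 0.4,
                          min_spikes = 3) {
  stopifnot(rate_fast > 0, rate_slow > 0, p_fast >= 0, p_fast <= 1)
  mean_gap <- p_fast / rate_fast + (1 - p_fast) / rate_slow
  if (duration / (mean_gap + exp(bd_ln_mean + bd_ln_sd^2 / 2)) < 1) {
    warning("expected burst count < 1 for this duration; proceeding")
  }
  starts <- numeric(0); ends <- numeric(0); counts <- integer(0)
  times <- vector("list", 0)
  t_cur <- 0
  repeat {
    fast <- stats::runif(1) < p_fast
    gap <- stats::rexp(1, if (fast) rate_fast else rate_slow)
    bd <- stats::rlnorm(1, bd_ln_mean, bd_ln_sd)
    start <- t_cur + gap
    if (start + bd > duration) break
    ibsr <- stats::rlnorm(1, ibsr_ln_mean, ibsr_ln_sd)
    n <- max(min_spikes, round(ibsr * bd))
    inner <- if (n > 2) sort(stats::runif(n - 2, 0, bd)) else numeric(0)
    spk <- start + c(0, inner, bd)
    starts <- c(starts, start); ends <- c(ends, start + bd)
    counts <- c(counts, n); times <- c(times, list(spk))
    t_cur <- start + bd
  }
  list(times = unlist(times),
       bursts = tibble::tibble(start_s = starts, end_s = ends,
                               n_spikes = counts))
}

#' Specification for a synthetic compartmentalized recording
#'
#' Bundles every generative parameter: per-region ISI power-law exponents
#' and bounds for the well trains, burst-process parameters, the tunnel
#' axon ground truth (signed conduction delays, sources, traffic shares),
#' planted well-axon rate couplings, recording noise (background spikes,
#' detection failures, delay jitter) and per-condition stimulation
#' modifiers.
#'
#' @param seed Integer RNG seed; `generate_recording()` calls `set.seed()`
#'   with it.
#' @param duration Recording length, seconds (default 300, the 5-min
#'   spontaneous recordings the device produces).
#' @param wells_per_region Electrodes per sub-regional well (<= 19).
#' @param isi_exponent Named numeric, ISI CCD slope per region (negative).
#' @param isi_range ISI sampling bounds `c(lo, hi)` in seconds.
#' @param well_mode `"renewal"` (bounded power-law ISI renewal trains, the
#'   default: short-ISI packets emerge from the heavy tail) or `"bursts"`
#'   (explicit [burst_process()] trains with log-normal BD/IBSR).
#' @param burst_rate_fast,burst_rate_slow,p_fast,bd_ln_mean,bd_ln_sd,ibsr_ln_mean,ibsr_ln_sd
#'   Parameters forwarded to [burst_process()] when `well_mode = "bursts"`.
#' @param tunnel_axons Tibble with one row per planted axon: `tunnel_id`,
#'   `axon_index`, `delay_ms` (signed; positive = feed-forward),
#'   `spike_fraction`, `source` (a well `electrode_id`, or `NA` for an
#'   independent axon process). `NULL` plants one independent axon per
#'   tunnel of the default layout with alternating-sign delays.
#' @param planted_edges Tibble of planted rate couplings: columns
#'   `well_electrode_id`, `tunnel_id`, `axon_index`, `influence`
#'   (`"well_to_axon"` or `"axon_to_well"`), `slope` (> 0), `noise_sd_hz`.
#'   `NULL` plants none.
#' @param axon_rate Target mean rate (Hz) of independent axon processes.
#' @param noise_rate Background (unpaired) spike rate per tunnel electrode,
#'   Hz.
#' @param detection_failure_p Probability a propagated spike is missed on
#'   one electrode (applied independently per electrode).
#' @param delay_jitter_sd Per-spike conduction-delay jitter SD, ms.
#' @param rate_factor Global thinning factor applied to generated trains
#'   (stimulation modifiers lower it below 1).
#' @param stim_modifiers Named list (`no_stim`, `hfs5`, `hfs40`) of lists
#'   with `rate_factor`, `exponent_factor`, `edge_keep_fraction`,
#'   `edge_noise_factor`; see [apply_stim_modifier()].
#' @param condition Condition label attached to generated recordings.
#' @return A list of class `synth_spec`.
#' @export
synth_spec <- function(seed = 1L,
                       duration = 300,
                       wells_per_region = 19,
                       isi_exponent = c(EC = -1.3, DG = -1.2,
                                        CA3 = -1.4, CA1 = -1.25),
                       isi_range = c(0.01, 10),
                       well_mode = c("renewal", "bursts"),
                       burst_rate_fast = 1, burst_rate_slow = 0.1,
                       p_fast = 0.7,
                       bd_ln_mean = log(0.05), bd_ln_sd = 0.5,
                       ibsr_ln_mean = log(150), ibsr_ln_sd = 0.4,
                       tunnel_axons = NULL,
                       planted_edges = NULL,
                       axon_rate = 8,
                       noise_rate = 0.5,
                       detection_failure_p = 0.02,
                       delay_jitter_sd = 0.02,
                       rate_factor = 1,
                       stim_modifiers = default_stim_modifiers(),
                       condition = "no_stim") {
  well_mode <- match.arg(well_mode)
  stopifnot(isi_range[1] > 0, isi_range[2] > isi_range[1],
            all(isi_exponent < 0),
            detection_failure_p >= 0, detection_failure_p <= 1,
            noise_rate >= 0, delay_jitter_sd >= 0, rate_factor > 0)
  if (!is.null(planted_edges)) {
    planted_edges <- tibble::as_tibble(planted_edges)
    stopifnot(all(planted_edges$slope > 0))
    # each rate series can follow a single planted driver
    wta <- planted_edges[planted_edges$influence == "well_to_axon", ]
    atw <- planted_edges[planted_edges$influence == "axon_to_well", ]
    if (anyDuplicated(paste(wta$tunnel_id, wta$axon_index)) ||
        anyDuplicated(atw$well_electrode_id)) {
      warning("multiple planted couplings drive the same target; ",
              "only the first per target takes effect")
    }
  }
  if (!is.null(tunnel_axons)) tunnel_axons <- tibble::as_tibble(tunnel_axons)
  structure(list(
    seed = seed, duration = duration, wells_per_region = wells_per_region,
    isi_exponent = isi_exponent, isi_range = isi_range,
    well_mode = well_mode,
    burst_rate_fast = burst_rate_fast, burst_rate_slow = burst_rate_slow,
    p_fast = p_fast, bd_ln_mean = bd_ln_mean, bd_ln_sd = bd_ln_sd,
    ibsr_ln_mean = ibsr_ln_mean, ibsr_ln_sd = ibsr_ln_sd,
    tunnel_axons = tunnel_axons, planted_edges = planted_edges,
    axon_rate = axon_rate, noise_rate = noise_rate,
    detection_failure_p = detection_failure_p,
    delay_jitter_sd = delay_jitter_sd, rate_factor = rate_factor,
    stim_modifiers = stim_modifiers, condition = condition),
    class = "synth_spec")
}

#' @rdname apply_stim_modifier
#' @export
default_stim_modifiers <- function() {
  list(
    no_stim = list(rate_factor = 1, exponent_factor = 1,
                   edge_keep_fraction = 1, edge_noise_factor = 1,
                   edge_slope_factor = 1),
    hfs5 = list(rate_factor = 0.8, exponent_factor = 0.85,
                edge_keep_fraction = 0.7, edge_noise_factor = 0.7,
                edge_slope_factor = 1.25),
    hfs40 = list(rate_factor = 0.6, exponent_factor = 0.7,
                 edge_keep_fraction = 0.45, edge_noise_factor = 0.5,
                 edge_slope_factor = 1.5))
}

#' Apply a stimulation-condition modifier to a synthetic spec
#'
#' High-frequency stimulation is modelled purely as a condition label with
#' parameter modifiers: rates are thinned (`rate_factor`), ISI CCD slopes
#' are shallowed (`exponent_factor` < 1 shrinks `|alpha|`) and the planted
#' rate couplings are sharpened: `edge_keep_fraction` prunes couplings in
#' order of decreasing relative noise (the unreliable routes are lost
#' first), the survivors' rate noise shrinks by `edge_noise_factor` and
#' their slopes grow by `edge_slope_factor` (route potentiation). Together
#' these emulate fewer but more reliable functional routes. `no_stim` is
#' the identity.
#'
#' @param spec A [synth_spec()].
#' @param condition `"no_stim"`, `"hfs5"` or `"hfs40"`.
#' @return The modified `synth_spec`, with `condition` set.
#' @export
apply_stim_modifier <- function(spec, condition) {
  stopifnot(inherits(spec, "synth_spec"))
  if (!condition %in% names(spec$stim_modifiers)) {
    stop("unknown condition: ", condition, call. = FALSE)
  }
  mod <- spec$stim_modifiers[[condition]]
  spec$condition <- condition
  spec$isi_exponent <- spec$isi_exponent * mod$exponent_factor
  spec$rate_factor <- spec$rate_factor * mod$rate_factor
  if (!is.null(spec$planted_edges) && nrow(spec$planted_edges)) {
    pe <- spec$planted_edges
    keep <- ceiling(mod$edge_keep_fraction * nrow(pe))
    ord <- order(pe$noise_sd_hz / pe$slope)
    pe <- pe[sort(ord[seq_len(keep)]), ]
    pe$noise_sd_hz <- pe$noise_sd_hz * mod$edge_noise_factor
    pe$slope <- pe$slope * (mod$edge_slope_factor %||% 1)
    spec$planted_edges <- pe
  }
  spec
}

default_tunnel_axons <- function(layout) {
  delays <- rep(c(0.5, -0.4, 0.7, -0.3, 0.6), length.out = nrow(layout$tunnels))
  tibble::tibble(tunnel_id = layout$tunnels$tunnel_id,
                 axon_index = 1L,
                 delay_ms = delays,
                 spike_fraction = 1,
                 source = NA_character_)
}

#' Generate a synthetic recording with planted ground truth
#'
#' Produces a full [mea_recording()] for a layout: per-well spike trains
#' with the specified ISI power-law structure, tunnel electrode pairs that
#' contain — for each planted axon — paired spikes offset by the axon's
#' signed conduction delay plus jitter (with detection failures and
#' Poisson background), and well/axon rate series satisfying the planted
#' linear couplings up to noise. Deterministic for a fixed `spec$seed`.
#'
#' @param spec A [synth_spec()].
#' @param layout An [mea_layout()]; `NULL` builds
#'   `default_layout(spec$wells_per_region)`.
#' @return List with `recording` (an `mea_recording`), `layout`, and
#'   `truth`: a list with `axons` (tibble incl. a list-column `events` of
#'   the true per-axon source spike times) and `edges` (the planted
#'   couplings).
#' @export
generate_recording <- function(spec, layout = NULL) {
  stopifnot(inherits(spec, "synth_spec"))
  if (is.null(layout)) layout <- default_layout(spec$wells_per_region)
  if (!is.null(spec$seed)) set.seed(spec$seed)
  dur <- spec$duration
  axons <- spec$tunnel_axons %||% default_tunnel_axons(layout)
  stopifnot(all(axons$tunnel_id %in% layout$tunnels$tunnel_id))
  edges <- spec$planted_edges %||%
    tibble::tibble(well_electrode_id = character(), tunnel_id = character(),
                   axon_index = integer(), influence = character(),
                   slope = numeric(), noise_sd_hz = numeric())
  bin_w <- 0.1
  n_bins <- floor(dur / bin_w)

  region_of <- stats::setNames(layout$wells$region, layout$wells$electrode_id)
  gen_well <- function(el) {
    alpha <- spec$isi_exponent[[region_of[[el]]]]
    if (spec$well_mode == "renewal") {
      powerlaw_train(dur, alpha, spec$isi_range, thin = spec$rate_factor)
    } else {
      bp <- burst_process(dur, spec$burst_rate_fast, spec$burst_rate_slow,
                          spec$p_fast, spec$bd_ln_mean, spec$bd_ln_sd,
                          spec$ibsr_ln_mean, spec$ibsr_ln_sd)
      t <- bp$times
      if (spec$rate_factor < 1) {
        t <- t[stats::runif(length(t)) < spec$rate_factor]
      }
      t
    }
  }
  rate_of <- function(times) {
    idx <- floor(times / bin_w) + 1
    tabulate(idx[idx >= 1 & idx <= n_bins], n_bins) / bin_w
  }
  inhom_poisson <- function(rate) {
    counts <- stats::rpois(n_bins, pmax(rate, 0) * bin_w)
    starts <- rep.int((seq_len(n_bins) - 1) * bin_w, counts)
    sort(starts + stats::runif(sum(counts), 0, bin_w))
  }

  # wells driven by an axon-to-well coupling are generated after their axon
  driven_wells <- edges$well_electrode_id[edges$influence == "axon_to_well"]
  well_ids <- layout$wells$electrode_id
  well_trains <- list()
  for (el in setdiff(well_ids, driven_wells)) well_trains[[el]] <- gen_well(el)

  axon_key <- function(tid, idx) paste0(tid, "#", idx)
  mean_alpha <- mean(spec$isi_exponent)
  axon_events <- list()
  for (k in seq_len(nrow(axons))) {
    a <- axons[k, ]
    key <- axon_key(a$tunnel_id, a$axon_index)
    drv <- edges[edges$influence == "well_to_axon" &
                   edges$tunnel_id == a$tunnel_id &
                   edges$axon_index == a$axon_index, ]
    if (nrow(drv)) {
      x <- rate_of(well_trains[[drv$well_electrode_id[1]]])
      target <- drv$slope[1] * x +
        stats::rnorm(n_bins, 0, drv$noise_sd_hz[1])
      ev <- inhom_poisson(target)
    } else if (!is.na(a$source)) {
      src <- well_trains[[a$source]]
      ev <- src[stats::runif(length(src)) < a$spike_fraction]
    } else {
      ev <- powerlaw_train(dur, mean_alpha, spec$isi_range,
                           thin = spec$rate_factor)
      raw_rate <- length(ev) / dur
      p <- min(1, spec$axon_rate * spec$rate_factor / max(raw_rate, 1e-9))
      ev <- ev[stats::runif(length(ev)) < p]
    }
    if (is.na(a$source) && a$spike_fraction < 1) {
      ev <- ev[stats::runif(length(ev)) < a$spike_fraction]
    }
    axon_events[[key]] <- ev
  }

  for (el in driven_wells) {
    e <- edges[edges$well_electrode_id == el &
                 edges$influence == "axon_to_well", ][1, ]
    x <- rate_of(axon_events[[axon_key(e$tunnel_id, e$axon_index)]])
    target <- e$slope * x + stats::rnorm(n_bins, 0, e$noise_sd_hz)
    well_trains[[el]] <- inhom_poisson(target)
  }

  # tunnel electrodes: delayed copies + detection failures + background
  tun_trains <- list()
  for (tid in unique(axons$tunnel_id)) {
    tun <- layout$tunnels[layout$tunnels$tunnel_id == tid, ]
    up <- numeric(0); dn <- numeric(0)
    sub <- axons[axons$tunnel_id == tid, ]
    for (k in seq_len(nrow(sub))) {
      a <- sub[k, ]
      ev <- axon_events[[axon_key(a$tunnel_id, a$axon_index)]]
      jit <- stats::rnorm(length(ev), 0, spec$delay_jitter_sd / 1000)
      keep_up <- stats::runif(length(ev)) >= spec$detection_failure_p
      keep_dn <- stats::runif(length(ev)) >= spec$detection_failure_p
      up <- c(up, ev[keep_up])
      dn <- c(dn, (ev + a$delay_ms / 1000 + jit)[keep_dn])
    }
    n_bg <- stats::rpois(2, spec$noise_rate * spec$rate_factor * dur)
    up <- c(up, stats::runif(n_bg[1], 0, dur))
    dn <- c(dn, stats::runif(n_bg[2], 0, dur))
    tun_trains[[tun$upstream_electrode]] <- sort(up[up >= 0 & up <= dur])
    tun_trains[[tun$downstream_electrode]] <- sort(dn[dn >= 0 & dn <= dur])
  }

  all_trains <- c(well_trains, tun_trains)
  spikes <- tibble::tibble(
    electrode_id = rep(names(all_trains), lengths(all_trains)),
    time_s = unlist(all_trains, use.names = FALSE))
  rec <- mea_recording(spikes, duration = dur, condition = spec$condition,
                       recording_id = paste0("synthetic_seed", spec$seed))
  truth_axons <- axons |>
    dplyr::mutate(
      direction = ifelse(.data$delay_ms > 0, "feed_forward", "feedback"),
      events = purrr::map2(.data$tunnel_id, .data$axon_index,
                           \(t, i) axon_events[[axon_key(t, i)]]),
      n_events = lengths(.data$events))
  list(recording = rec, layout = layout,
       truth = list(axons = truth_axons, edges = edges))
}

#' Simulate a full three-condition stimulation experiment
#'
#' Applies each condition's stimulation modifier to `spec` and generates
#' one recording per condition (with condition-specific sub-seeds derived
#' from `spec$seed`).
#'
#' @param spec A [synth_spec()] describing the unstimulated culture.
#' @param layout Optional [mea_layout()].
#' @param conditions Condition labels to simulate.
#' @return Named list (by condition) of [generate_recording()] results.
#' @export
simulate_experiment <- function(spec, layout = NULL,
                                conditions = c("no_stim", "hfs5", "hfs40")) {
  out <- list()
  for (i in seq_along(conditions)) {
    cond_spec <- apply_stim_modifier(spec, conditions[i])
    cond_spec$seed <- spec$seed + 1000L * (i - 1L)
    out[[conditions[i]]] <- generate_recording(cond_spec, layout)
  }
  out
}
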