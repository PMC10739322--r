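#' Conduction-delay histogram of a tunnel's paired spikes
#'
#' Signed delays are binned over `[-range_ms, +range_ms]`. The default
#' 0.04 ms bin width resolves the +-0.16 ms axon merge radius with four
#' bins per radius. Counts are conserved: every pair falls in exactly one
#' bin.
#'
#' @param pairs A `spike_pairs` object with at least one pair.
#' @param bin_width_ms Bin width in milliseconds.
#' @param range_ms Half-range of the histogram in milliseconds.
#' @return List of class `delay_histogram`: `bin_edges_ms`,
#'   `bin_centers_ms`, `counts`, `n_pairs`, `bin_width_ms`.
#' @export
build_delay_histogram <- function(pairs, bin_width_ms = 0.04,
                                  range_ms = 1.0) {
  stopifnot(inherits(pairs, "spike_pairs"), bin_width_ms > 0)
  if (!nrow(pairs)) {
    stop("no pairable activity: cannot build a delay histogram",
         call. = FALSE)
  }
  edges <- seq(-range_ms, range_ms, by = bin_width_ms)
  if (edges[length(edges)] < range_ms) edges <- c(edges, range_ms)
  idx <- findInterval(pairs$delay_ms, edges, rightmost.closed = TRUE,
                      all.inside = TRUE)
  counts <- tabulate(idx, length(edges) - 1L)
  structure(list(bin_edges_ms = edges,
                 bin_centers_ms = (edges[-1] + edges[-length(edges)]) / 2,
                 counts = counts, n_pairs = nrow(pairs),
                 bin_width_ms = bin_width_ms),
            class = "delay_histogram")
}

# topographic prominence of a local maximum: height above the higher of the
# two interval minima, each interval extending to the nearest strictly
# higher bin; no pairs exist outside the binned delay window, so the
# signal is zero-padded at both ends
peak_prominences <- function(counts, peaks) {
  vapply(peaks, function(i) {
    h <- counts[i]
    left <- counts[seq_len(i - 1L)]
    hi_l <- which(left > h)
    base_l <- if (length(hi_l)) min(counts[(max(hi_l) + 1L):(i - 1L)]) else 0
    right <- if (i < length(counts)) counts[(i + 1L):length(counts)] else
      numeric(0)
    hi_r <- which(right > h)
    base_r <- if (length(hi_r)) min(right[seq_len(min(hi_r) - 1L)]) else 0
    h - max(base_l, base_r)
  }, numeric(1))
}

local_maxima <- function(counts) {
  r <- rle(counts)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  k <- length(r$values)
  is_peak <- r$values > c(-Inf, r$values[-k]) &
    r$values > c(r$values[-1], -Inf) & r$values > 0
  starts[is_peak]
}

#' Detect axons as peaks of the conduction-delay histogram
#'
#' Each axon in a tunnel conducts at a characteristic velocity, so its
#' paired spikes pile up at one signed delay. Peaks qualify as axons when
#' their bin count exceeds `mean + sd_threshold * SD` of all bin counts
#' (default 1.9 SD) and their topographic prominence is at least
#' `prominence_frac` of the highest bin (default 12%). Qualifying maxima
#' closer than `merge_radius_ms` (default 0.16 ms) are merged, keeping the
#' taller; each pair is then assigned to the nearest surviving peak within
#' the merge radius (others stay unassigned). Peaks with `|delay|` below
#' the pairing window's lower edge are admitted down to
#' `fast_floor_ms` (default 0.12 ms) when `admit_fast` is on — sufficiently
#' fast conduction is real if a clear peak is there — and rejected below
#' the floor. Positive peak delay means feed-forward, negative feedback.
#'
#' @param hist A `delay_histogram`.
#' @param pairs The `spike_pairs` the histogram was built from.
#' @param sd_threshold Count threshold in SD units above the mean bin count.
#' @param prominence_frac Minimum prominence as a fraction of the highest
#'   bin.
#' @param merge_radius_ms Peaks closer than this are one axon.
#' @param fast_floor_ms Smallest admissible `|peak delay|`.
#' @param admit_fast Admit peaks between `fast_floor_ms` and
#'   `window_min_ms`.
#' @param window_min_ms Lower edge of the standard physiological delay
#'   window; with `admit_fast` off, peaks below it are rejected.
#' @return A tibble of class `axon_assignments` with one row per axon:
#'   `axon_index`, `peak_delay_ms`, `direction`, `n_spikes`, `peak_height`;
#'   attribute `assignment` maps each pair (row of `pairs`) to an
#'   `axon_index` or `NA`. Zero qualifying peaks give a zero-row tibble.
#' @export
detect_axon_peaks <- function(hist, pairs,
                              sd_threshold = 1.9,
                              prominence_frac = 0.12,
                              merge_radius_ms = 0.16,
                              fast_floor_ms = 0.12,
                              admit_fast = TRUE, window_min_ms = 0.2) {
  stopifnot(inherits(hist, "delay_histogram"), inherits(pairs, "spike_pairs"))
  counts <- hist$counts
  centers <- hist$bin_centers_ms
  floor_ms <- if (admit_fast) fast_floor_ms else window_min_ms
  cand <- local_maxima(counts)
  cand <- cand[abs(centers[cand]) >= floor_ms]
  empty <- tibble::tibble(axon_index = integer(0), peak_delay_ms = numeric(0),
                          direction = character(0), n_spikes = integer(0),
                          peak_height = numeric(0))
  gate <- mean(counts) + sd_threshold * stats::sd(counts)
  keep <- counts[cand] > gate &
    peak_prominences(counts, cand) >= prominence_frac * max(counts)
  cand <- cand[keep]
  if (!length(cand)) {
    return(structure(empty, class = c("axon_assignments", class(empty)),
                     assignment = rep(NA_integer_, nrow(pairs))))
  }
  # merge maxima within the radius, tallest wins (tie: faster conduction)
  ord <- order(-counts[cand], abs(centers[cand]))
  accepted <- integer(0)
  for (i in cand[ord]) {
    if (!length(accepted) ||
        all(abs(centers[i] - centers[accepted]) > merge_radius_ms + 1e-9)) {
      accepted <- c(accepted, i)
    }
  }
  accepted <- accepted[order(centers[accepted])]
  peak_delay <- centers[accepted]
  # nearest-peak assignment within the merge radius
  assignment <- rep(NA_integer_, nrow(pairs))
  if (nrow(pairs)) {
    d <- abs(outer(pairs$delay_ms, peak_delay, "-"))
    nearest <- max.col(-d, ties.method = "first")
    within <- d[cbind(seq_len(nrow(pairs)), nearest)] <= merge_radius_ms
    assignment[within] <- nearest[within]
  }
  axons <- tibble::tibble(
    axon_index = seq_along(accepted),
    peak_delay_ms = peak_delay,
    direction = ifelse(peak_delay > 0, "feed_forward", "feedback"),
    n_spikes = as.integer(tabulate(assignment, length(accepted))),
    peak_height = counts[accepted])
  structure(axons, class = c("axon_assignments", class(axons)),
            assignment = assignment)
}

#' Per-axon spike trains
#'
#' Splits a tunnel's paired spikes into one train per detected axon, using
#' each axon's member pairs' upstream spike times. Trains are sorted and
#' disjoint across axons; unassigned pairs belong to no train.
#'
#' @param axons An `axon_assignments` tibble from [detect_axon_peaks()].
#' @param pairs The matching `spike_pairs`.
#' @return Named list (by `axon_index`) of sorted spike-time vectors.
#' @export
axon_spike_trains <- function(axons, pairs) {
  stopifnot(inherits(axons, "axon_assignments"))
  assignment <- attr(axons, "assignment")
  out <- lapply(axons$axon_index, function(i) {
    sort(pairs$up_time_s[!is.na(assignment) & assignment == i])
  })
  stats::setNames(out, as.character(axons$axon_index))
}

#' Infer axons and directions for every tunnel of a recording
#'
#' End-to-end direction stage: for each tunnel in the layout, pair the two
#' electrodes' spikes, compute the NMI validity gate, and — for valid
#' tunnels — build the conduction-delay histogram and detect directional
#' axon peaks.
#'
#' @param recording An [mea_recording()].
#' @param layout An [mea_layout()].
#' @param window_ms Pairing delay-magnitude window, ms.
#' @param nmi_threshold Tunnel validity gate on NMI.
#' @param bin_width_ms Delay histogram bin width, ms.
#' @inheritParams detect_axon_peaks
#' @return List of class `axon_inference`: `axons` (tibble: `tunnel_id`,
#'   `wall`, `axon_index`, `peak_delay_ms`, `direction`, `n_spikes`),
#'   `tunnels` (tibble: per-tunnel `nmi`, `valid`, `n_pairs`, `n_up`,
#'   `n_down`), and `trains` (named list `tunnel_id#axon_index` of per-axon
#'   spike trains).
#' @export
infer_axons <- function(recording, layout,
                        window_ms = c(0.2, 1.0), nmi_threshold = 0.2,
                        bin_width_ms = 0.04, sd_threshold = 1.9,
                        prominence_frac = 0.12, merge_radius_ms = 0.16,
                        fast_floor_ms = 0.12, admit_fast = TRUE) {
  stopifnot(inherits(recording, "mea_recording"),
            inherits(layout, "mea_layout"))
  pair_lo <- if (admit_fast) min(fast_floor_ms, window_ms[1]) else window_ms[1]
  tun <- layout$tunnels
  tun_rows <- list(); axon_rows <- list(); trains <- list()
  for (k in seq_len(nrow(tun))) {
    t <- tun[k, ]
    up <- spike_train(recording, t$upstream_electrode)
    down <- spike_train(recording, t$downstream_electrode)
    pairs <- match_spike_pairs(up, down, c(pair_lo, window_ms[2]))
    nres <- compute_nmi(pairs, nmi_threshold)
    tun_rows[[k]] <- tibble::tibble(
      tunnel_id = t$tunnel_id, wall = t$wall, nmi = nres$nmi,
      valid = nres$valid, n_pairs = nres$n_pairs, n_up = nres$n_up,
      n_down = nres$n_down)
    if (!isTRUE(nres$valid) || !nrow(pairs)) next
    hist <- build_delay_histogram(pairs, bin_width_ms, range_ms = window_ms[2])
    axons <- detect_axon_peaks(hist, pairs, sd_threshold, prominence_frac,
                               merge_radius_ms, fast_floor_ms, admit_fast,
                               window_min_ms = window_ms[1])
    if (!nrow(axons)) next
    axon_rows[[k]] <- dplyr::mutate(axons, tunnel_id = t$tunnel_id,
                                    wall = t$wall, .before = 1)
    tr <- axon_spike_trains(axons, pairs)
    names(tr) <- paste0(t$tunnel_id, "#", axons$axon_index)
    trains <- c(trains, tr)
  }
  axons_tbl <- if (length(axon_rows)) {
    purrr::list_rbind(purrr::map(purrr::compact(axon_rows),
                                 tibble::as_tibble))
  } else {
    tibble::tibble(tunnel_id = character(0), wall = character(0),
                   axon_index = integer(0), peak_delay_ms = numeric(0),
                   direction = character(0), n_spikes = integer(0),
                   peak_height = numeric(0))
  }
  structure(list(axons = axons_tbl,
                 tunnels = purrr::list_rbind(tun_rows),
                 trains = trains),
            class = "axon_inference")
}
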