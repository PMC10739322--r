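#' Pair spikes across a tunnel's two electrodes
#'
#' A spike propagating through a microfluidic tunnel appears on both
#' electrodes separated by its conduction time over the inter-electrode
#' distance (0.2 mm by default). Candidate pairs are all (upstream,
#' downstream) spike combinations whose signed delay `t_down - t_up` has
#' magnitude inside `window_ms` (default 0.2-1 ms, the physiological
#' propagation bounds; both signs are considered). Matching is greedy
#' one-to-one by smallest `|delay|`, ties broken by earlier upstream time,
#' so no spike is reused — one spike, one propagation.
#'
#' @param up,down Sorted spike-time vectors (seconds) of the upstream and
#'   downstream tunnel electrodes (upstream in the feed-forward sense).
#' @param window_ms `c(min, max)` delay-magnitude window in milliseconds.
#' @return A tibble of class `spike_pairs` with columns `up_time_s` and
#'   `delay_ms` (signed: positive = feed-forward), sorted by time, plus
#'   attributes `n_up`, `n_down` and `window_ms`. Empty trains give an
#'   empty pair set.
#' @export
match_spike_pairs <- function(up, down, window_ms = c(0.2, 1.0)) {
  stopifnot(length(window_ms) == 2, window_ms[1] >= 0,
            window_ms[2] > window_ms[1])
  w_lo <- window_ms[1] / 1000
  w_hi <- window_ms[2] / 1000
  empty <- tibble::tibble(up_time_s = numeric(0), delay_ms = numeric(0))
  if (!length(up) || !length(down)) {
    return(structure(empty, class = c("spike_pairs", class(empty)),
                     n_up = length(up), n_down = length(down),
                     window_ms = window_ms))
  }
  # candidate (i, j) with |down[j] - up[i]| in [w_lo, w_hi]
  j_lo <- findInterval(up - w_hi, down) + 1L
  j_hi <- findInterval(up + w_hi, down)
  n_cand <- pmax(0L, j_hi - j_lo + 1L)
  has <- n_cand > 0L
  i_idx <- rep.int(seq_along(up)[has], n_cand[has])
  j_idx <- sequence(n_cand[has], from = j_lo[has])
  delta <- down[j_idx] - up[i_idx]
  ok <- abs(delta) >= w_lo & abs(delta) <= w_hi
  i_idx <- i_idx[ok]; j_idx <- j_idx[ok]; delta <- delta[ok]
  if (length(i_idx)) {
    ord <- order(abs(delta), up[i_idx])
    used_up <- logical(length(up))
    used_dn <- logical(length(down))
    take <- logical(length(ord))
    for (k in ord) {
      i <- i_idx[k]; j <- j_idx[k]
      if (!used_up[i] && !used_dn[j]) {
        used_up[i] <- TRUE; used_dn[j] <- TRUE; take[k] <- TRUE
      }
    }
    i_idx <- i_idx[take]; delta <- delta[take]
  }
  pairs <- tibble::tibble(up_time_s = up[i_idx], delay_ms = delta * 1000) |>
    dplyr::arrange(.data$up_time_s)
  structure(pairs, class = c("spike_pairs", class(pairs)),
            n_up = length(up), n_down = length(down), window_ms = window_ms)
}

#' Normalized matching index of a tunnel
#'
#' `NMI = n_paired / max(n_up, n_down)`: the fraction of spikes of the
#' busier tunnel electrode that found a partner on the other electrode. A
#' tunnel is considered valid for axon identification when NMI exceeds the
#' threshold (strictly; default 0.2), which suppresses spurious spike-pair
#' correlations during high spike rates. NMI is computed from raw pairable
#' spikes, before any axon peak assignment.
#'
#' @param pairs A `spike_pairs` object from [match_spike_pairs()].
#' @param threshold Validity gate (default 0.2).
#' @return List of class `nmi_result`: `nmi` (in `[0, 1]`, `NA` if both
#'   trains are empty), `valid`, `n_pairs`, `n_up`, `n_down`, `threshold`,
#'   and `reason` when invalid.
#' @export
compute_nmi <- function(pairs, threshold = 0.2) {
  stopifnot(inherits(pairs, "spike_pairs"))
  n_up <- attr(pairs, "n_up"); n_down <- attr(pairs, "n_down")
  denom <- max(n_up, n_down)
  if (denom == 0) {
    out <- list(nmi = NA_real_, valid = FALSE, n_pairs = 0L,
                n_up = n_up, n_down = n_down, threshold = threshold,
                reason = "both trains empty")
  } else {
    nmi <- nrow(pairs) / denom
    out <- list(nmi = nmi, valid = nmi > threshold, n_pairs = nrow(pairs),
                n_up = n_up, n_down = n_down, threshold = threshold,
                reason = if (nmi > threshold) NA_character_ else
                  "NMI at or below validity threshold")
  }
  structure(out, class = "nmi_result")
}
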