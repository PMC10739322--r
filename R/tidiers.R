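#' Tidy and glance methods for fitted objects
#'
#' Every fit in the package — power-law CCD fits, piecewise inter-burst
#' fits, log-normal fits, effect sizes and test results — has `tidy()`
#' (one row per estimated term or segment) and `glance()` (a one-row
#' model summary) methods, so fit collections assemble naturally with
#' `purrr::map()` + `dplyr::bind_rows()`.
#'
#' @param x A fitted object.
#' @param ... Unused.
#' @return A tibble.
#' @name axotrace-tidiers
NULL

#' @rdname axotrace-tidiers
#' @export
tidy.power_law_fit <- function(x, ...) {
  tibble::tibble(term = c("alpha", "c"), estimate = c(x$alpha, x$c))
}

#' @rdname axotrace-tidiers
#' @export
glance.power_law_fit <- function(x, ...) {
  tibble::tibble(alpha = x$alpha, c = x$c, r2 = x$r2,
                 t_lo = x$fit_window[1], t_hi = x$fit_window[2],
                 n_bins = x$n_bins)
}

#' @rdname axotrace-tidiers
#' @export
tidy.piecewise_ibi_fit <- function(x, ...) {
  dplyr::bind_rows(
    dplyr::mutate(glance(x$fast), segment = "fast", .before = 1),
    dplyr::mutate(glance(x$slow), segment = "slow", .before = 1))
}

#' @rdname axotrace-tidiers
#' @export
glance.piecewise_ibi_fit <- function(x, ...) {
  tibble::tibble(crossover_s = x$crossover,
                 alpha_fast = x$fast$alpha, alpha_slow = x$slow$alpha,
                 r2_fast = x$fast$r2, r2_slow = x$slow$r2)
}

#' @rdname axotrace-tidiers
#' @export
tidy.lognormal_fit <- function(x, ...) {
  tibble::tibble(term = c("m", "s"), estimate = c(x$m, x$s))
}

#' @rdname axotrace-tidiers
#' @export
glance.lognormal_fit <- function(x, ...) {
  tibble::tibble(m = x$m, s = x$s, median = x$median, r2 = x$r2)
}

#' @rdname axotrace-tidiers
#' @export
tidy.effect_size <- function(x, ...) {
  tibble::tibble(d = x$d, ci_lo = x$ci[1], ci_hi = x$ci[2], band = x$band,
                 significant = x$significant)
}

#' @rdname axotrace-tidiers
#' @export
glance.effect_size <- tidy.effect_size

#' @rdname axotrace-tidiers
#' @export
tidy.test_result <- function(x, ...) {
  if (is.null(x$pairwise)) {
    return(tibble::tibble(statistic = x$statistic, p_value = x$p_value,
                          reject = x$reject))
  }
  dplyr::mutate(x$pairwise, statistic = x$statistic, p_value = x$p_value)
}

#' @rdname axotrace-tidiers
#' @export
glance.test_result <- function(x, ...) {
  tibble::tibble(statistic = x$statistic, p_value = x$p_value,
                 alpha = x$alpha, reject = x$reject, method = x$method)
}

#' @rdname axotrace-tidiers
#' @export
tidy.nmi_result <- function(x, ...) {
  tibble::tibble(nmi = x$nmi, valid = x$valid, n_pairs = x$n_pairs,
                 n_up = x$n_up, n_down = x$n_down)
}

#' @rdname axotrace-tidiers
#' @export
tidy.axon_inference <- function(x, ...) x$axons

#' @rdname axotrace-tidiers
#' @export
glance.axon_inference <- function(x, ...) {
  tibble::tibble(n_tunnels = nrow(x$tunnels),
                 n_valid = sum(x$tunnels$valid),
                 n_axons = nrow(x$axons),
                 n_feed_forward = sum(x$axons$direction == "feed_forward"),
                 n_feedback = sum(x$axons$direction == "feedback"))
}

#' @rdname axotrace-tidiers
#' @export
tidy.slope_comparison <- function(x, ...) x$delta

#' @rdname axotrace-tidiers
#' @export
tidy.graph_metrics <- function(x, ...) x$nodes
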