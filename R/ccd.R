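#' Complementary cumulative distribution on logarithmic bins
#'
#' `P(t)` is the fraction of values at least `t`, evaluated at `n_bins`
#' logarithmically spaced points spanning the data range and normalized so
#' the smallest bin has `P = 1`. On log-log axes a power-law tail is a
#' straight line whose slope the fits below estimate.
#'
#' @param values Positive values (intervals in seconds, or spike counts for
#'   spikes-per-burst).
#' @param n_bins Number of log-spaced evaluation points (>= 10).
#' @return A tibble of class `ccd` with columns `t` and `p` (`p`
#'   non-increasing, `p[1] == 1`).
#' @export
compute_ccd <- function(values, n_bins = 50) {
  if (!length(values)) stop("cannot build a CCD from no values",
                            call. = FALSE)
  stopifnot(all(values > 0), n_bins >= 10)
  lo <- min(values); hi <- max(values)
  t <- if (hi > lo) exp(seq(log(lo), log(hi), length.out = n_bins)) else lo
  t[1] <- lo
  v <- sort(values)
  n <- length(v)
  # count of v >= t_i via the sorted sample
  p <- (n - findInterval(t, v, left.open = TRUE)) / n
  p <- p / p[1]
  out <- tibble::tibble(t = t, p = p)
  structure(out, class = c("ccd", class(out)), n_values = n)
}

fast_line_fit <- function(lx, ly) {
  mx <- mean(lx); my <- mean(ly)
  vx <- sum((lx - mx)^2)
  cxy <- sum((lx - mx) * (ly - my))
  vy <- sum((ly - my)^2)
  slope <- cxy / vx
  list(slope = slope, intercept = my - slope * mx,
       r2 = if (vy > 0) cxy^2 / (vx * vy) else 1)
}

new_power_law_fit <- function(alpha, c, r2, fit_window, prob_window,
                              n_bins) {
  structure(list(alpha = alpha, c = c, r2 = r2,
                 fit_window = fit_window, prob_window = prob_window,
                 n_bins = n_bins),
            class = "power_law_fit")
}

#' Fit a power law to a CCD by grid-searched linear regression
#'
#' Fits `log10(P) = alpha * log10(t) + c` by least squares over bins inside
#' both a time window and a probability window. Following the
#' grid-search rule, each endpoint of the default time window is scaled
#' multiplicatively over `[1 - max_frac, 1 + max_frac]` in `step_frac`
#' increments (defaults 50% and 5%, a 21 x 21 grid) and the window with the
#' highest Pearson R-squared wins; ties go to the widest window, then the
#' smallest lower limit. With `grid_max_frac = 0` the fit is the plain
#' full-window regression.
#'
#' @param ccd A `ccd` tibble from [compute_ccd()].
#' @param fit_window Default time window `c(lo, hi)` in the value's units
#'   (the conventional interval window is 0.01-1 s; EC-DG feed-forward ISI
#'   distributions are non-linear there and use 0.1-0.2 s instead).
#' @param prob_window Probability window `c(lo, hi)` filtering bins before
#'   the time grid (default keeps `P` from 1 down to 0.1).
#' @param grid_max_frac Maximum fractional variation of each endpoint.
#' @param grid_step_frac Grid step as a fraction.
#' @param grid_scan Which endpoints the grid scans: both (default), only
#'   the lower, or only the upper (used by the piecewise fit, whose
#'   crossover endpoint is pinned).
#' @return A `power_law_fit`: `alpha` (slope), `c` (intercept), `r2`,
#'   `fit_window` (the winning window), `prob_window`, `n_bins` used.
#' @export
fit_power_law <- function(ccd, fit_window = c(0.01, 1.0),
                          prob_window = c(0.1, 1),
                          grid_max_frac = 0.5, grid_step_frac = 0.05,
                          grid_scan = c("both", "lo", "hi")) {
  grid_scan <- match.arg(grid_scan)
  stopifnot(inherits(ccd, "ccd"))
  keep <- ccd$p > 0 & ccd$p >= prob_window[1] & ccd$p <= prob_window[2]
  t <- ccd$t[keep]; p <- ccd$p[keep]
  if (length(t) < 3) stop("fewer than 3 CCD bins inside the probability ",
                          "window", call. = FALSE)
  lx <- log10(t); ly <- log10(p)
  fac <- if (grid_max_frac > 0) {
    seq(1 - grid_max_frac, 1 + grid_max_frac, by = grid_step_frac)
  } else 1
  fac_lo <- if (grid_scan %in% c("both", "lo")) fac else 1
  fac_hi <- if (grid_scan %in% c("both", "hi")) fac else 1
  best <- NULL
  for (f1 in fac_lo) {
    lo <- fit_window[1] * f1
    for (f2 in fac_hi) {
      hi <- fit_window[2] * f2
      if (hi <= lo) next
      inw <- lx >= log10(lo) & lx <= log10(hi)
      if (sum(inw) < 3) next
      fit <- fast_line_fit(lx[inw], ly[inw])
      cand <- list(fit = fit, lo = lo, hi = hi, n = sum(inw))
      if (is.null(best)) { best <- cand; next }
      dr2 <- fit$r2 - best$fit$r2
      better <- dr2 > 1e-12 ||
        (abs(dr2) <= 1e-12 &&
           ((cand$hi - cand$lo) - (best$hi - best$lo) > 1e-12 ||
              (abs((cand$hi - cand$lo) - (best$hi - best$lo)) <= 1e-12 &&
                 cand$lo < best$lo - 1e-15)))
      if (better) best <- cand
    }
  }
  if (is.null(best)) {
    stop("no candidate time window contains at least 3 CCD bins",
         call. = FALSE)
  }
  new_power_law_fit(best$fit$slope, best$fit$intercept, best$fit$r2,
                    c(best$lo, best$hi), prob_window, best$n)
}

#' Piecewise power-law fit for inter-burst intervals
#'
#' Inter-burst interval CCDs show two regimes: fast bursting ("up states")
#' at short intervals and slow bursting ("down states") at long ones. For
#' each candidate crossover, a fast segment is fitted below it and a slow
#' segment above it (each with the endpoint grid search of
#' [fit_power_law()], the crossover endpoint pinned so the fast window's
#' maximum equals the slow window's minimum); the crossover maximizing the
#' summed R-squared wins and is then refined to the intersection point of
#' the two fitted lines (refitting both segments at each step until the
#' intersection is stable).
#'
#' @param ccd A `ccd` from [compute_ccd()] of inter-burst intervals.
#' @param candidate_crossovers Candidate break points, seconds; `NULL`
#'   takes `n_candidates` log-spaced points inside the data range, leaving
#'   at least 3 bins on each side.
#' @param n_candidates Number of default candidates.
#' @param prob_window Probability filter. The default spans the two orders
#'   of probability the inter-burst plots cover (`P` from 1 down to 0.01),
#'   which keeps the slow tail fittable while excluding the few-sample
#'   extreme tail.
#' @inheritParams fit_power_law
#' @return A `piecewise_ibi_fit`: `fast` and `slow` (`power_law_fit`s) and
#'   `crossover` (s).
#' @export
fit_piecewise_ibi <- function(ccd, candidate_crossovers = NULL,
                              n_candidates = 25, prob_window = c(0.01, 1),
                              grid_max_frac = 0.5, grid_step_frac = 0.05) {
  stopifnot(inherits(ccd, "ccd"))
  tt <- ccd$t[ccd$p > 0 & ccd$p >= prob_window[1] & ccd$p <= prob_window[2]]
  if (length(tt) < 7) stop("too few CCD bins for a piecewise fit",
                           call. = FALSE)
  if (is.null(candidate_crossovers)) {
    lo <- tt[4]; hi <- tt[length(tt) - 3]
    if (hi <= lo) stop("CCD does not span two regimes", call. = FALSE)
    candidate_crossovers <- exp(seq(log(lo), log(hi),
                                    length.out = n_candidates))
  }
  best <- NULL
  for (cr in candidate_crossovers) {
    fast <- try(fit_power_law(ccd, fit_window = c(min(tt), cr),
                              prob_window = prob_window,
                              grid_max_frac = grid_max_frac,
                              grid_step_frac = grid_step_frac,
                              grid_scan = "lo"), silent = TRUE)
    slow <- try(fit_power_law(ccd, fit_window = c(cr, max(tt)),
                              prob_window = prob_window,
                              grid_max_frac = grid_max_frac,
                              grid_step_frac = grid_step_frac,
                              grid_scan = "hi"), silent = TRUE)
    if (inherits(fast, "try-error")) {
      stop("too few bins below candidate crossover ", signif(cr, 3), " s",
           call. = FALSE)
    }
    if (inherits(slow, "try-error")) {
      stop("too few bins above candidate crossover ", signif(cr, 3), " s",
           call. = FALSE)
    }
    score <- fast$r2 + slow$r2
    if (is.null(best) || score > best$score) {
      best <- list(score = score, fast = fast, slow = slow, crossover = cr)
    }
  }
  # refine: the crossover is the intersection of the two fitted lines
  cr <- best$crossover
  fast <- best$fast; slow <- best$slow
  for (i in seq_len(6)) {
    denom <- fast$alpha - slow$alpha
    if (abs(denom) < 1e-9) break
    tstar <- 10^((slow$c - fast$c) / denom)
    tstar <- max(min(tstar, tt[length(tt) - 3]), tt[4])
    if (abs(log(tstar / cr)) < 0.01) break
    cr <- tstar
    fast2 <- try(fit_power_law(ccd, fit_window = c(min(tt), cr),
                               prob_window = prob_window,
                               grid_max_frac = grid_max_frac,
                               grid_step_frac = grid_step_frac,
                               grid_scan = "lo"), silent = TRUE)
    slow2 <- try(fit_power_law(ccd, fit_window = c(cr, max(tt)),
                               prob_window = prob_window,
                               grid_max_frac = grid_max_frac,
                               grid_step_frac = grid_step_frac,
                               grid_scan = "hi"), silent = TRUE)
    if (inherits(fast2, "try-error") || inherits(slow2, "try-error")) break
    fast <- fast2; slow <- slow2
  }
  structure(list(fast = fast, slow = slow, crossover = cr),
            class = "piecewise_ibi_fit")
}

#' Log-normal fit in natural-log space
#'
#' Fits a normal distribution to the probability density of `ln(values)`
#' (histogram with the Freedman-Diaconis rule, then a Gaussian
#' least-squares fit), as used for burst durations and intraburst spike
#' rates. The distribution median is `exp(m)` exactly.
#'
#' @param values Positive values (n >= 10 unless degenerate).
#' @return A `lognormal_fit`: `m` (ln-mean), `s` (ln-SD), `median`
#'   (`exp(m)`, value units), `r2` of the Gaussian fit.
#' @export
fit_lognormal <- function(values) {
  if (any(values <= 0)) stop("log-normal fit requires positive values",
                             call. = FALSE)
  x <- log(values)
  if (length(unique(values)) == 1) {
    return(structure(list(m = x[1], s = 0, median = values[1], r2 = 1),
                     class = "lognormal_fit"))
  }
  stopifnot(length(values) >= 10)
  h <- graphics::hist(x, breaks = "FD", plot = FALSE)
  dens <- h$density; mids <- h$mids
  m0 <- mean(x); s0 <- stats::sd(x)
  fit <- try(stats::nls(dens ~ stats::dnorm(mids, m, s),
                        start = list(m = m0, s = s0),
                        lower = c(-Inf, 1e-8),
                        algorithm = "port",
                        control = stats::nls.control(warnOnly = TRUE)),
             silent = TRUE)
  if (inherits(fit, "try-error")) {
    m <- m0; s <- s0
    pred <- stats::dnorm(mids, m, s)
  } else {
    cf <- stats::coef(fit)
    m <- unname(cf["m"]); s <- unname(cf["s"])
    pred <- stats::predict(fit)
  }
  ss_res <- sum((dens - pred)^2)
  ss_tot <- sum((dens - mean(dens))^2)
  structure(list(m = m, s = s, median = exp(m),
                 r2 = if (ss_tot > 0) max(0, 1 - ss_res / ss_tot) else 1),
            class = "lognormal_fit")
}

#' Compare fitted CCD slopes across conditions and directions
#'
#' Summarizes a table of power-law fits: percent slope change of each
#' stimulation condition against the unstimulated baseline,
#' `100 * (|alpha_cond| - |alpha_base|) / |alpha_base|` — negative means a
#' shallower (decreased) slope — and, where both directions are present,
#' the feed-forward versus feedback fractional difference
#' `100 * (|alpha_ff| - |alpha_fb|) / |alpha_fb|` (positive = excess
#' feed-forward slope).
#'
#' @param fits Tibble with columns `group` (e.g. region or wall,
#'   optionally split by direction), `condition`, optionally `direction`,
#'   and `alpha`.
#' @param baseline Baseline condition label (default `"no_stim"`).
#' @return A `slope_comparison`: `delta` (tibble of per-group, per-condition
#'   `delta_percent`) and `ff_fb` (tibble of per-group, per-condition
#'   `ff_fb_fraction`; zero rows when `direction` is absent).
#' @export
compare_slopes <- function(fits, baseline = "no_stim") {
  fits <- tibble::as_tibble(fits)
  stopifnot(all(c("group", "condition", "alpha") %in% names(fits)))
  if (!baseline %in% fits$condition) {
    stop("missing baseline condition '", baseline, "'", call. = FALSE)
  }
  keys <- intersect(c("group", "direction"), names(fits))
  base <- fits |>
    dplyr::filter(.data$condition == baseline) |>
    dplyr::select(dplyr::all_of(keys), alpha_base = "alpha")
  delta <- fits |>
    dplyr::inner_join(base, by = keys) |>
    dplyr::mutate(delta_percent =
                    100 * (abs(.data$alpha) - abs(.data$alpha_base)) /
                    abs(.data$alpha_base)) |>
    dplyr::select(dplyr::all_of(keys), "condition", "alpha",
                  "delta_percent")
  ff_fb <- tibble::tibble(group = character(0), condition = character(0),
                          ff_fb_fraction = numeric(0))
  if ("direction" %in% names(fits)) {
    wide <- fits |>
      dplyr::select("group", "condition", "direction", "alpha") |>
      tidyr::pivot_wider(names_from = "direction", values_from = "alpha")
    if (all(c("feed_forward", "feedback") %in% names(wide))) {
      ff_fb <- wide |>
        dplyr::filter(!is.na(.data$feed_forward), !is.na(.data$feedback)) |>
        dplyr::mutate(ff_fb_fraction =
                        100 * (abs(.data$feed_forward) - abs(.data$feedback)) /
                        abs(.data$feedback)) |>
        dplyr::select("group", "condition", "ff_fb_fraction")
    }
  }
  structure(list(delta = delta, ff_fb = ff_fb, baseline = baseline),
            class = "slope_comparison")
}
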