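#' Binned firing-rate series
#'
#' Average firing rate per fixed-width bin (default 100 ms). The series has
#' `floor(duration / bin_width)` bins; spikes beyond the last full bin are
#' dropped so every bin has equal width. `sum(rate * bin_width)` equals the
#' number of spikes inside the covered span.
#'
#' @param times Sorted spike-time vector, seconds.
#' @param bin_width_s Bin width, seconds.
#' @param duration_s Recording duration, seconds.
#' @return Tibble with `t_s` (bin start) and `rate` (spikes/s).
#' @export
bin_rates <- function(times, bin_width_s = 0.1, duration_s) {
  stopifnot(bin_width_s > 0, duration_s > 0)
  tibble::tibble(t_s = (seq_len(floor(duration_s / bin_width_s)) - 1) *
                   bin_width_s,
                 rate = rate_vector(times, bin_width_s, duration_s))
}

rate_vector <- function(times, bin_width_s, duration_s) {
  n_bins <- floor(duration_s / bin_width_s)
  idx <- floor(times / bin_width_s) + 1
  tabulate(idx[idx >= 1 & idx <= n_bins], n_bins) / bin_width_s
}

# rolling-window first and second moments via cumulative sums
roll_sums <- function(v, w) {
  cv <- c(0, cumsum(v))
  n <- length(v)
  cv[(w + 1):(n + 1)] - cv[1:(n - w + 1)]
}

#' Sliding-window rate regressions between two series
#'
#' Slides a window (default 10 s) over two equal-length binned rate series
#' in single-bin steps (default 100 ms) and, in every window where each
#' series has at least `min_nonzero_bins` non-zero bins, regresses the
#' target rate on the source rate by ordinary least squares. Windows that
#' would run past the end of the series are dropped, not truncated.
#'
#' @param source,target Rate tibbles from [bin_rates()] (equal bin width
#'   and length), or bare numeric rate vectors.
#' @param window_s Window width, seconds.
#' @param bin_width_s Bin width of the series, seconds.
#' @param min_nonzero_bins Non-zero-bin requirement, applied to each series
#'   separately.
#' @return Tibble with one row per window position: `window_start_s`,
#'   `slope`, `r2`, `n_nonzero_bins` (the smaller of the two series'
#'   counts), `qualifies`. `slope`/`r2` are `NA` in non-qualifying or
#'   degenerate (zero-variance) windows.
#' @export
windowed_regressions <- function(source, target, window_s = 10,
                                 bin_width_s = 0.1, min_nonzero_bins = 4) {
  x <- if (is.data.frame(source)) source$rate else source
  y <- if (is.data.frame(target)) target$rate else target
  if (length(x) != length(y)) {
    stop("source and target rate series have different lengths",
         call. = FALSE)
  }
  w <- as.integer(round(window_s / bin_width_s))
  stopifnot(w >= 2, length(x) >= w)
  st <- roll_stats(x, y, w, min_nonzero_bins)
  tibble::tibble(window_start_s = (seq_len(length(st$slope)) - 1) *
                   bin_width_s,
                 slope = ifelse(st$qual, st$slope, NA_real_),
                 r2 = ifelse(st$qual, st$r2, NA_real_),
                 n_nonzero_bins = st$n_nonzero,
                 qualifies = st$qual)
}

roll_stats <- function(x, y, w, min_nonzero_bins) {
  sx <- roll_sums(x, w); sy <- roll_sums(y, w)
  sxx <- roll_sums(x * x, w); syy <- roll_sums(y * y, w)
  sxy <- roll_sums(x * y, w)
  nzx <- roll_sums(as.numeric(x > 0), w)
  nzy <- roll_sums(as.numeric(y > 0), w)
  vx <- sxx - sx^2 / w
  vy <- syy - sy^2 / w
  cxy <- sxy - sx * sy / w
  qual <- nzx >= min_nonzero_bins & nzy >= min_nonzero_bins &
    vx > 1e-12 & vy > 1e-12
  list(slope = ifelse(vx > 1e-12, cxy / vx, NA_real_),
       slope_rev = ifelse(vy > 1e-12, cxy / vy, NA_real_),
       r2 = ifelse(vx > 1e-12 & vy > 1e-12, cxy^2 / (vx * vy), NA_real_),
       n_nonzero = pmin(nzx, nzy), qual = qual)
}

#' Connectivity analysis parameters
#'
#' Defaults mirror the published analysis: 100 ms rate bins, a 10-s sliding
#' window advanced in 100-ms steps, at least 4 non-zero bins per series,
#' and edge gates mean slope > 0.1 with mean R-squared > 0.2.
#'
#' @param bin_width_s Rate bin width, s.
#' @param window_s Sliding-window width, s.
#' @param min_nonzero_bins Non-zero-bin requirement per series.
#' @param slope_gate,r2_gate Retention gates on the window-averaged slope
#'   and R-squared.
#' @param gate_per_window If `TRUE`, gate each window's slope/R-squared
#'   before averaging instead of gating the averages (never yields more
#'   edges than the default).
#' @return List of class `connectivity_params`.
#' @export
connectivity_params <- function(bin_width_s = 0.1, window_s = 10,
                                min_nonzero_bins = 4, slope_gate = 0.1,
                                r2_gate = 0.2, gate_per_window = FALSE) {
  stopifnot(bin_width_s > 0, window_s > bin_width_s, min_nonzero_bins >= 1)
  structure(list(bin_width_s = bin_width_s, window_s = window_s,
                 min_nonzero_bins = min_nonzero_bins,
                 slope_gate = slope_gate, r2_gate = r2_gate,
                 gate_per_window = gate_per_window),
            class = "connectivity_params")
}

#' Build the directed well-axon functional-connectivity edge list
#'
#' For every ordered (well electrode, tunnel axon) combination in both
#' orientations — well to axon and axon to well — the sliding-window
#' regressions of [windowed_regressions()] are averaged over qualifying
#' windows and the averaged connection is kept as an edge when it passes
#' both gates (positive mean slope above `slope_gate`, mean R-squared above
#' `r2_gate`). A slope below 1 reads as a damped rate through the
#' connection, above 1 as amplification; the mean R-squared is the edge's
#' reliability. The axon's rate series uses the spikes assigned to that
#' axon, timed on the more active of the tunnel's two electrodes (some
#' electrodes couple weakly to the axon). Each edge inherits the axon's
#' transmission direction as its `direction_class`.
#'
#' @param recording An [mea_recording()].
#' @param layout An [mea_layout()].
#' @param inference An `axon_inference` from [infer_axons()].
#' @param params A [connectivity_params()].
#' @return Tibble with one row per retained edge: `source`, `target`,
#'   `orientation` (`"well_to_axon"` / `"axon_to_well"`), `tunnel_id`,
#'   `axon_index`, `direction_class`, `mean_slope`, `mean_r2`, `n_windows`.
#' @export
build_edges <- function(recording, layout, inference,
                        params = connectivity_params()) {
  stopifnot(inherits(inference, "axon_inference"))
  dur <- recording_duration(recording)
  bw <- params$bin_width_s
  w <- as.integer(round(params$window_s / bw))
  axons <- inference$axons
  if (!nrow(axons) || floor(dur / bw) < w) return(empty_edges())

  well_ids <- layout$wells$electrode_id
  well_rates <- lapply(well_ids, function(el) {
    rate_vector(spike_train(recording, el), bw, dur)
  })
  names(well_rates) <- well_ids

  tun <- layout$tunnels
  axon_rates <- vector("list", nrow(axons))
  for (k in seq_len(nrow(axons))) {
    a <- axons[k, ]
    t <- tun[tun$tunnel_id == a$tunnel_id, ]
    n_up <- length(spike_train(recording, t$upstream_electrode))
    n_dn <- length(spike_train(recording, t$downstream_electrode))
    key <- paste0(a$tunnel_id, "#", a$axon_index)
    times <- inference$trains[[key]]
    # member times are upstream by construction; shift to the more active
    # electrode when that is the downstream one
    if (n_dn > n_up) times <- times + a$peak_delay_ms / 1000
    axon_rates[[k]] <- rate_vector(times, bw, dur)
  }

  rows <- list(); ri <- 1L
  for (k in seq_len(nrow(axons))) {
    ay <- axon_rates[[k]]
    for (el in well_ids) {
      st <- roll_stats(well_rates[[el]], ay, w, params$min_nonzero_bins)
      for (orient in c("well_to_axon", "axon_to_well")) {
        slopes <- if (orient == "well_to_axon") st$slope else st$slope_rev
        e <- average_edge(slopes, st$r2, st$qual, params)
        if (is.null(e)) next
        rows[[ri]] <- tibble::tibble(
          source = if (orient == "well_to_axon") el else
            paste0(axons$tunnel_id[k], "#", axons$axon_index[k]),
          target = if (orient == "well_to_axon")
            paste0(axons$tunnel_id[k], "#", axons$axon_index[k]) else el,
          orientation = orient,
          tunnel_id = axons$tunnel_id[k],
          axon_index = axons$axon_index[k],
          direction_class = axons$direction[k],
          mean_slope = e$slope, mean_r2 = e$r2, n_windows = e$n)
        ri <- ri + 1L
      }
    }
  }
  if (!length(rows)) return(empty_edges())
  purrr::list_rbind(rows)
}

average_edge <- function(slopes, r2, qual, params) {
  ok <- qual & is.finite(slopes) & is.finite(r2)
  if (params$gate_per_window) {
    ok <- ok & slopes > params$slope_gate & r2 > params$r2_gate
  }
  if (!any(ok)) return(NULL)
  ms <- mean(slopes[ok]); mr <- mean(r2[ok])
  if (!(ms > params$slope_gate && mr > params$r2_gate)) return(NULL)
  list(slope = ms, r2 = mr, n = sum(ok))
}

empty_edges <- function() {
  tibble::tibble(source = character(0), target = character(0),
                 orientation = character(0), tunnel_id = character(0),
                 axon_index = integer(0), direction_class = character(0),
                 mean_slope = numeric(0), mean_r2 = numeric(0),
                 n_windows = integer(0))
}

#' Degree and centrality metrics of the connectivity graph
#'
#' Per node and direction class: in/out degree (edge counts), slope
#' centrality (sum of incident mean slopes) and R-squared centrality (sum
#' of incident mean R-squared, the node's aggregate reliability), each
#' split by incoming/outgoing edges. For a well electrode, "in" aggregates
#' axon-to-well edges and "out" well-to-axon edges. Per direction class the
#' handshake identity holds: total in-degree = total out-degree = number of
#' edges.
#'
#' @param edges Edge tibble from [build_edges()].
#' @param layout Optional [mea_layout()]; when given, zero-degree well
#'   electrodes are included and per-region aggregates are computed.
#' @return List of class `graph_metrics`: `nodes` (tibble: `node`,
#'   `node_type`, `direction_class`, `degree_in`, `degree_out`,
#'   `slope_centrality_in/out`, `r2_centrality_in/out`) and `regions`
#'   (per sub-region x orientation x direction class means over well
#'   electrodes; zero-row tibble without a layout).
#' @export
graph_metrics <- function(edges, layout = NULL) {
  classes <- c("feed_forward", "feedback")
  nodes_known <- unique(c(edges$source, edges$target))
  if (!is.null(layout)) {
    nodes_known <- unique(c(nodes_known, layout$wells$electrode_id))
  }
  if (!length(nodes_known)) {
    nodes_known <- character(0)
  }
  grid <- tidyr::expand_grid(node = nodes_known, direction_class = classes)
  agg <- function(df, role) {
    key <- if (role == "in") "target" else "source"
    df |>
      dplyr::group_by(node = .data[[key]], .data$direction_class) |>
      dplyr::summarise(degree = dplyr::n(),
                       slope_centrality = sum(.data$mean_slope),
                       r2_centrality = sum(.data$mean_r2),
                       .groups = "drop") |>
      dplyr::rename_with(\(nm) paste0(nm, "_", role),
                         c("degree", "slope_centrality", "r2_centrality"))
  }
  nodes <- grid |>
    dplyr::left_join(agg(edges, "in"), by = c("node", "direction_class")) |>
    dplyr::left_join(agg(edges, "out"), by = c("node", "direction_class")) |>
    dplyr::mutate(dplyr::across(dplyr::where(is.numeric),
                                \(v) tidyr::replace_na(v, 0)),
                  degree_in = as.integer(.data$degree_in),
                  degree_out = as.integer(.data$degree_out))
  if (!is.null(layout)) {
    region_map <- stats::setNames(layout$wells$region,
                                  layout$wells$electrode_id)
    nodes <- nodes |>
      dplyr::mutate(node_type = ifelse(
        .data$node %in% layout$wells$electrode_id, "well", "axon"),
        region = unname(region_map[.data$node]),
        .after = "node")
    regions <- nodes |>
      dplyr::filter(.data$node_type == "well") |>
      tidyr::pivot_longer(
        cols = c("degree_in", "degree_out", "slope_centrality_in",
                 "slope_centrality_out", "r2_centrality_in",
                 "r2_centrality_out"),
        names_to = c("metric", "orientation"),
        names_pattern = "(.*)_(in|out)$") |>
      dplyr::group_by(.data$region, .data$orientation,
                      .data$direction_class, .data$metric) |>
      dplyr::summarise(mean_per_node = mean(.data$value),
                       .groups = "drop")
  } else {
    nodes <- dplyr::mutate(nodes, node_type = NA_character_,
                           region = NA_character_, .after = "node")
    regions <- tibble::tibble(region = character(0),
                              orientation = character(0),
                              direction_class = character(0),
                              metric = character(0),
                              mean_per_node = numeric(0))
  }
  structure(list(nodes = nodes, regions = regions),
            class = "graph_metrics")
}

#' Feed-forward / feedback balance across stimulation conditions
#'
#' Summarizes how the network's directed routing changes with stimulation.
#' Per condition, sub-region and orientation it contrasts feed-forward
#' against feedback well-node metrics (degrees, slope centrality,
#' R-squared centrality) with Cohen's d and its 95% CI (an effect is
#' meaningful when the CI excludes zero); per condition and direction class
#' it reports edge counts, mean reliability (edge R-squared), and — against
#' the unstimulated baseline — the percent reliability change, summarized
#' as mean +- SE over sub-region x orientation cells with a one-tailed
#' t-test for an increase above no change.
#'
#' @param metrics_by_condition Named list (condition) of [graph_metrics()]
#'   results (with layout-based regions).
#' @param edges_by_condition Named list (condition) of edge tibbles.
#' @param baseline Baseline condition (default `"no_stim"`).
#' @return List of class `balance_summary`: `effects`, `reliability`,
#'   `reliability_change` tibbles and `reliability_test` (per direction
#'   class `test_result`s; `NULL` without a baseline).
#' @export
balance_summary <- function(metrics_by_condition, edges_by_condition,
                            baseline = "no_stim") {
  conds <- names(metrics_by_condition)
  if (length(conds) < 2) {
    stop("balance_summary needs metrics for at least 2 conditions",
         call. = FALSE)
  }
  effects <- purrr::imap(metrics_by_condition, function(gm, cond) {
    nodes <- gm$nodes |> dplyr::filter(.data$node_type == "well")
    if (!nrow(nodes)) return(NULL)
    # contrast ff vs fb values across each sub-region's well electrodes
    nodes |>
      tidyr::pivot_longer(
        cols = c("degree_in", "degree_out", "slope_centrality_in",
                 "slope_centrality_out", "r2_centrality_in",
                 "r2_centrality_out"),
        names_to = c("metric", "orientation"),
        names_pattern = "(.*)_(in|out)$") |>
      dplyr::group_by(.data$region, .data$metric, .data$orientation) |>
      dplyr::group_modify(\(df, key) {
        ff <- df$value[df$direction_class == "feed_forward"]
        fb <- df$value[df$direction_class == "feedback"]
        es <- tryCatch(cohens_d(ff, fb), error = function(e) NULL)
        if (is.null(es)) {
          return(tibble::tibble(d = NA_real_, ci_lo = NA_real_,
                                ci_hi = NA_real_, band = NA_character_,
                                significant = NA))
        }
        tibble::tibble(d = es$d, ci_lo = es$ci[1], ci_hi = es$ci[2],
                       band = es$band, significant = es$significant)
      }) |>
      dplyr::ungroup() |>
      dplyr::mutate(condition = cond, .before = 1)
  }) |> purrr::compact() |> purrr::list_rbind()

  reliability <- purrr::imap(edges_by_condition, function(ed, cond) {
    if (!nrow(ed)) {
      return(tibble::tibble(condition = cond,
                            direction_class = c("feed_forward", "feedback"),
                            n_edges = 0L, mean_r2 = NA_real_,
                            mean_slope = NA_real_))
    }
    ed |>
      dplyr::group_by(.data$direction_class) |>
      dplyr::summarise(n_edges = dplyr::n(),
                       mean_r2 = mean(.data$mean_r2),
                       mean_slope = mean(.data$mean_slope),
                       .groups = "drop") |>
      dplyr::mutate(condition = cond, .before = 1)
  }) |> purrr::list_rbind()

  reliability_change <- tibble::tibble()
  reliability_test <- NULL
  if (baseline %in% names(edges_by_condition)) {
    base_cells <- edge_reliability_cells(edges_by_condition[[baseline]])
    changes <- purrr::imap(
      edges_by_condition[setdiff(names(edges_by_condition), baseline)],
      function(ed, cond) {
        cells <- edge_reliability_cells(ed)
        dplyr::inner_join(cells, base_cells,
                          by = c("direction_class", "tunnel_id"),
                          suffix = c("", "_base")) |>
          dplyr::mutate(
            pct_change = 100 * (.data$mean_r2 - .data$mean_r2_base) /
              .data$mean_r2_base,
            condition = cond)
      }) |> purrr::list_rbind()
    if (nrow(changes)) {
      reliability_change <- changes |>
        dplyr::group_by(.data$condition, .data$direction_class) |>
        dplyr::summarise(mean_pct = mean(.data$pct_change),
                         se_pct = stats::sd(.data$pct_change) /
                           sqrt(dplyr::n()),
                         n_cells = dplyr::n(), .groups = "drop")
      reliability_test <- changes |>
        dplyr::group_by(.data$direction_class) |>
        dplyr::group_map(\(df, key) {
          list(direction_class = key$direction_class,
               test = if (nrow(df) >= 2) {
                 one_tailed_t(df$pct_change, "greater")
               })
        })
    }
  }
  structure(list(effects = effects, reliability = reliability,
                 reliability_change = reliability_change,
                 reliability_test = reliability_test,
                 baseline = baseline),
            class = "balance_summary")
}

# per-tunnel, per-direction mean edge reliability (the cells compared
# across conditions)
edge_reliability_cells <- function(edges) {
  if (!nrow(edges)) {
    return(tibble::tibble(direction_class = character(0),
                          tunnel_id = character(0), mean_r2 = numeric(0)))
  }
  edges |>
    dplyr::group_by(.data$direction_class, .data$tunnel_id) |>
    dplyr::summarise(mean_r2 = mean(.data$mean_r2), .groups = "drop")
}
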