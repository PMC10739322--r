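#' Full-pipeline configuration
#'
#' Bundles every stage's parameters with defaults mirroring the published
#' analysis: pairing window 0.2-1 ms, NMI gate 0.2, peak threshold 1.9 SD,
#' prominence 12%, merge radius 0.16 ms, fast-delay floor 0.12 ms; burst
#' detection 100 ms / 3 spikes; ISI fit window 0.01-1 s with probability
#' window 1 down to 0.1 and a 50%/5% endpoint grid (EC-DG feed-forward
#' axons use 0.1-0.2 s); rate bins 0.1 s, 10 s windows, 100 ms steps,
#' >= 4 non-zero bins, slope gate 0.1, R-squared gate 0.2.
#'
#' @param window_ms,nmi_threshold,bin_width_ms,sd_threshold,prominence_frac,merge_radius_ms,fast_floor_ms,admit_fast
#'   Direction-stage parameters; see [infer_axons()].
#' @param max_isi_s,min_spikes Burst detection; see [detect_bursts()].
#' @param isi_window,prob_window,grid_max_frac,grid_step_frac Power-law
#'   fit; see [fit_power_law()].
#' @param ecdg_ff_window Special ISI fit window for EC-DG feed-forward
#'   axons, seconds.
#' @param ccd_bins CCD bin count.
#' @param connectivity A [connectivity_params()].
#' @param baseline Baseline condition for comparisons.
#' @return List of class `pipeline_config`.
#' @export
pipeline_config <- function(window_ms = c(0.2, 1.0), nmi_threshold = 0.2,
                            bin_width_ms = 0.04, sd_threshold = 1.9,
                            prominence_frac = 0.12, merge_radius_ms = 0.16,
                            fast_floor_ms = 0.12, admit_fast = TRUE,
                            max_isi_s = 0.1, min_spikes = 3,
                            isi_window = c(0.01, 1.0),
                            prob_window = c(0.1, 1),
                            grid_max_frac = 0.5, grid_step_frac = 0.05,
                            ecdg_ff_window = c(0.1, 0.2),
                            ccd_bins = 50,
                            connectivity = connectivity_params(),
                            baseline = "no_stim") {
  structure(list(window_ms = window_ms, nmi_threshold = nmi_threshold,
                 bin_width_ms = bin_width_ms, sd_threshold = sd_threshold,
                 prominence_frac = prominence_frac,
                 merge_radius_ms = merge_radius_ms,
                 fast_floor_ms = fast_floor_ms, admit_fast = admit_fast,
                 max_isi_s = max_isi_s, min_spikes = min_spikes,
                 isi_window = isi_window, prob_window = prob_window,
                 grid_max_frac = grid_max_frac,
                 grid_step_frac = grid_step_frac,
                 ecdg_ff_window = ecdg_ff_window, ccd_bins = ccd_bins,
                 connectivity = connectivity, baseline = baseline),
            class = "pipeline_config")
}

pooled_isi <- function(trains) {
  unlist(lapply(trains, interval_series, statistic = "isi"),
         use.names = FALSE)
}

safe_fit <- function(expr) tryCatch(expr, error = function(e) NULL)

# distribution fits for one condition: pooled per region (wells) and per
# wall x direction (axons)
condition_dynamics <- function(recording, layout, inference, config) {
  region_groups <- split(layout$wells$electrode_id, layout$wells$region)
  well_trains <- lapply(region_groups, function(ids) {
    lapply(ids, function(el) spike_train(recording, el))
  })
  isi_fits <- list(); ln_fits <- list(); ibi_fits <- list()
  for (region in names(well_trains)) {
    trains <- well_trains[[region]]
    isis <- pooled_isi(trains)
    fit <- safe_fit(fit_power_law(compute_ccd(isis, config$ccd_bins),
                                  config$isi_window, config$prob_window,
                                  config$grid_max_frac,
                                  config$grid_step_frac))
    if (!is.null(fit)) {
      isi_fits[[length(isi_fits) + 1L]] <- tibble::tibble(
        group = region, kind = "well", direction = NA_character_,
        statistic = "isi", alpha = fit$alpha, c = fit$c, r2 = fit$r2,
        n = length(isis))
    }
    bursts <- lapply(trains, detect_bursts, max_isi_s = config$max_isi_s,
                     min_spikes = config$min_spikes)
    ibis <- unlist(lapply(bursts, interval_series, statistic = "ibi"),
                   use.names = FALSE)
    pw <- if (length(ibis) >= 30) {
      safe_fit(fit_piecewise_ibi(compute_ccd(ibis, config$ccd_bins),
                                 grid_max_frac = config$grid_max_frac,
                                 grid_step_frac = config$grid_step_frac))
    }
    if (!is.null(pw)) {
      ibi_fits[[length(ibi_fits) + 1L]] <- tibble::tibble(
        group = region, crossover_s = pw$crossover,
        alpha_fast = pw$fast$alpha, alpha_slow = pw$slow$alpha,
        r2_fast = pw$fast$r2, r2_slow = pw$slow$r2, n = length(ibis))
    }
    for (stat in c("bd", "ibsr")) {
      vals <- unlist(lapply(bursts, interval_series, statistic = stat),
                     use.names = FALSE)
      ln <- if (length(vals) >= 10) safe_fit(fit_lognormal(vals))
      if (!is.null(ln)) {
        ln_fits[[length(ln_fits) + 1L]] <- tibble::tibble(
          group = region, statistic = stat, m = ln$m, s = ln$s,
          median = ln$median, r2 = ln$r2, n = length(vals))
      }
    }
  }
  # axon ISI fits pooled per wall x direction
  ax <- inference$axons
  if (nrow(ax)) {
    for (wall in unique(ax$wall)) {
      for (dirn in unique(ax$direction[ax$wall == wall])) {
        sel <- ax$wall == wall & ax$direction == dirn
        keys <- paste0(ax$tunnel_id[sel], "#", ax$axon_index[sel])
        isis <- pooled_isi(inference$trains[keys])
        if (length(isis) < 30) next
        win <- if (wall == "EC_DG" && dirn == "feed_forward") {
          config$ecdg_ff_window
        } else config$isi_window
        fit <- safe_fit(fit_power_law(compute_ccd(isis, config$ccd_bins),
                                      win, config$prob_window,
                                      config$grid_max_frac,
                                      config$grid_step_frac))
        if (!is.null(fit)) {
          isi_fits[[length(isi_fits) + 1L]] <- tibble::tibble(
            group = wall, kind = "axon", direction = dirn,
            statistic = "isi", alpha = fit$alpha, c = fit$c, r2 = fit$r2,
            n = length(isis))
        }
      }
    }
  }
  list(isi_fits = purrr::list_rbind(isi_fits),
       ibi_fits = purrr::list_rbind(ibi_fits),
       lognormal_fits = purrr::list_rbind(ln_fits))
}

#' Run the full analysis pipeline over one or more conditions
#'
#' For each condition: infer tunnel axons and directions, fit the
#' spiking/bursting distributions (pooled ISI power laws per sub-region
#' and per wall x direction, piecewise inter-burst-interval fits,
#' log-normal burst duration and intraburst spike rate), and build the
#' directed well-axon connectivity graph with node metrics. Across
#' conditions it adds percent slope changes versus the baseline and the
#' feed-forward/feedback degree, weight and reliability balance.
#'
#' @param recordings Named list (by condition) of [mea_recording()]s.
#' @param layout An [mea_layout()].
#' @param config A [pipeline_config()].
#' @return List of class `pipeline_result`: `per_condition` (each with
#'   `inference`, `dynamics`, `edges`, `metrics`), `slope_comparison`,
#'   `balance`, and a cross-condition `summary` tibble.
#' @export
run_pipeline <- function(recordings, layout, config = pipeline_config()) {
  stopifnot(length(recordings) >= 1, !is.null(names(recordings)))
  per_condition <- purrr::imap(recordings, function(rec, cond) {
    stopifnot(inherits(rec, "mea_recording"))
    inference <- infer_axons(rec, layout,
                             window_ms = config$window_ms,
                             nmi_threshold = config$nmi_threshold,
                             bin_width_ms = config$bin_width_ms,
                             sd_threshold = config$sd_threshold,
                             prominence_frac = config$prominence_frac,
                             merge_radius_ms = config$merge_radius_ms,
                             fast_floor_ms = config$fast_floor_ms,
                             admit_fast = config$admit_fast)
    dynamics <- condition_dynamics(rec, layout, inference, config)
    edges <- build_edges(rec, layout, inference, config$connectivity)
    metrics <- graph_metrics(edges, layout)
    list(inference = inference, dynamics = dynamics, edges = edges,
         metrics = metrics)
  })
  conds <- names(per_condition)
  isi_all <- purrr::imap(per_condition, \(pc, cond)
                         dplyr::mutate(pc$dynamics$isi_fits,
                                       condition = cond)) |>
    purrr::list_rbind()
  slope_cmp <- if (config$baseline %in% conds && length(conds) >= 2) {
    safe_fit(compare_slopes(isi_all, config$baseline))
  }
  balance <- if (length(conds) >= 2) {
    balance_summary(purrr::map(per_condition, "metrics"),
                    purrr::map(per_condition, "edges"),
                    baseline = config$baseline)
  }
  summary_tbl <- purrr::imap(per_condition, function(pc, cond) {
    well_isi <- pc$dynamics$isi_fits
    well_isi <- well_isi[well_isi$kind == "well", ]
    tibble::tibble(
      condition = cond,
      n_valid_tunnels = sum(pc$inference$tunnels$valid),
      n_axons = nrow(pc$inference$axons),
      n_feed_forward = sum(pc$inference$axons$direction == "feed_forward"),
      n_edges = nrow(pc$edges),
      mean_edge_slope = if (nrow(pc$edges)) mean(pc$edges$mean_slope)
        else NA_real_,
      mean_edge_r2 = if (nrow(pc$edges)) mean(pc$edges$mean_r2)
        else NA_real_,
      mean_well_isi_alpha = if (nrow(well_isi)) mean(well_isi$alpha)
        else NA_real_)
  }) |> purrr::list_rbind()
  structure(list(per_condition = per_condition,
                 slope_comparison = slope_cmp, balance = balance,
                 summary = summary_tbl, config = config),
            class = "pipeline_result")
}

#' One-command synthetic demonstration
#'
#' Generates a three-condition synthetic experiment (stimulation modifiers
#' thin rates, shallow ISI slopes and prune/denoise planted couplings) and
#' runs the full pipeline on it.
#'
#' @param seed RNG seed.
#' @param spec Optional [synth_spec()]; the default plants one axon per
#'   tunnel and a dozen well-to-axon couplings.
#' @param config A [pipeline_config()].
#' @return List: `pipeline` (a `pipeline_result`), `experiment` (the
#'   generated recordings and truth bundles), `layout`.
#' @export
run_synthetic_demo <- function(seed = 1L, spec = NULL,
                               config = pipeline_config()) {
  layout <- default_layout()
  if (is.null(spec)) {
    axons <- default_tunnel_axons(layout)
    wells <- layout$wells$electrode_id
    planted <- tibble::tibble(
      well_electrode_id = wells[seq(1, 67, by = 6)],
      tunnel_id = layout$tunnels$tunnel_id[seq(1, 20, length.out = 12)],
      axon_index = 1L,
      influence = "well_to_axon",
      slope = rep(c(1.5, 1.0, 0.7), 4),
      noise_sd_hz = 3)
    spec <- synth_spec(seed = seed, duration = 300, tunnel_axons = axons,
                       planted_edges = planted)
  } else {
    spec$seed <- seed
  }
  experiment <- simulate_experiment(spec, layout)
  recs <- purrr::map(experiment, "recording")
  list(pipeline = run_pipeline(recs, layout, config),
       experiment = experiment, layout = layout)
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat("<pipeline_result> conditions:",
      paste(names(x$per_condition), collapse = ", "), "\n")
  print(x$summary)
  invisible(x)
}
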