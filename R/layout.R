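#' Array layout: wells, tunnels, spacing, plating orientation
#'
#' An `mea_layout` describes the geometry of a four-compartment
#' multi-electrode array: which electrodes sit in which sub-regional well
#' (EC, DG, CA3, CA1), which electrode pairs span the inter-regional
#' microfluidic tunnels, the inter-electrode distance inside a tunnel, and
#' the plating orientation (clockwise or counterclockwise around the
#' trisynaptic loop).
#'
#' The upstream/downstream order of each tunnel's electrode pair encodes the
#' feed-forward convention EC > DG > CA3 > CA1 > EC: a spike that appears on
#' the upstream electrode before the downstream one (positive conduction
#' delay) travels feed-forward. Axons crossing the CA1_EC wall in the
#' EC-to-CA1 sense are labelled feedback for internal consistency of the
#' loop convention.
#'
#' @param wells Data frame (or tibble) with columns `region` (one of
#'   `"EC"`, `"DG"`, `"CA3"`, `"CA1"`) and `electrode_id` (character).
#' @param tunnels Data frame with columns `tunnel_id`, `wall` (one of
#'   `"EC_DG"`, `"DG_CA3"`, `"CA3_CA1"`, `"CA1_EC"`), `upstream_electrode`,
#'   `downstream_electrode`.
#' @param electrode_spacing_mm Distance between the two tunnel electrodes in
#'   millimetres (default 0.2).
#' @param orientation Plating orientation, `"CW"` or `"CCW"`. Recorded for
#'   provenance; no analysis step depends on it.
#'
#' @return An object of class `mea_layout`: a list with tibbles `wells` and
#'   `tunnels` plus the spacing and orientation.
#' @export
mea_layout <- function(wells, tunnels,
                       electrode_spacing_mm = 0.2,
                       orientation = c("CW", "CCW")) {
  orientation <- match.arg(orientation)
  wells <- tibble::as_tibble(wells)
  tunnels <- tibble::as_tibble(tunnels)
  stopifnot(all(c("region", "electrode_id") %in% names(wells)),
            all(c("tunnel_id", "wall", "upstream_electrode",
                  "downstream_electrode") %in% names(tunnels)))
  layout <- structure(
    list(wells = wells[, c("region", "electrode_id")],
         tunnels = tunnels[, c("tunnel_id", "wall", "upstream_electrode",
                               "downstream_electrode")],
         electrode_spacing_mm = electrode_spacing_mm,
         orientation = orientation),
    class = "mea_layout")
  validate_layout(layout)
}

regions_canonical <- c("EC", "DG", "CA3", "CA1")
walls_canonical <- c("EC_DG", "DG_CA3", "CA3_CA1", "CA1_EC")

#' @rdname mea_layout
#' @param layout An `mea_layout`.
#' @export
validate_layout <- function(layout) {
  wells <- layout$wells
  tunnels <- layout$tunnels
  if (!all(wells$region %in% regions_canonical)) {
    bad <- setdiff(unique(wells$region), regions_canonical)
    stop("unknown sub-region(s): ", paste(bad, collapse = ", "), call. = FALSE)
  }
  if (!all(tunnels$wall %in% walls_canonical)) {
    bad <- setdiff(unique(tunnels$wall), walls_canonical)
    stop("unknown tunnel wall(s): ", paste(bad, collapse = ", "), call. = FALSE)
  }
  per_region <- table(wells$region)
  if (any(per_region > 19)) {
    stop("a sub-regional well lists more than 19 electrodes", call. = FALSE)
  }
  if (anyDuplicated(wells$electrode_id)) {
    stop("duplicated well electrode id", call. = FALSE)
  }
  tun_ids <- c(tunnels$upstream_electrode, tunnels$downstream_electrode)
  if (anyDuplicated(tun_ids)) {
    stop("an electrode appears in more than one tunnel role", call. = FALSE)
  }
  if (anyDuplicated(tunnels$tunnel_id)) {
    stop("duplicated tunnel_id", call. = FALSE)
  }
  overlap <- intersect(wells$electrode_id, tun_ids)
  if (length(overlap)) {
    stop("electrode(s) listed both in a well and a tunnel: ",
         paste(overlap, collapse = ", "), call. = FALSE)
  }
  if (!is.numeric(layout$electrode_spacing_mm) ||
      layout$electrode_spacing_mm <= 0) {
    stop("electrode_spacing_mm must be > 0", call. = FALSE)
  }
  layout
}

#' Default four-compartment layout
#'
#' Builds the canonical device geometry: 4 sub-regional wells with 19
#' electrodes each (76 well electrodes) and 4 tunnel walls with 5 monitored
#' tunnels each, every tunnel spanned by an upstream/downstream electrode
#' pair spaced 0.2 mm apart (40 tunnel electrodes).
#'
#' @param n_well_electrodes Electrodes per sub-regional well (<= 19).
#' @param n_tunnels_per_wall Monitored tunnels per wall.
#' @param orientation Plating orientation label.
#' @return An [mea_layout()].
#' @export
default_layout <- function(n_well_electrodes = 19, n_tunnels_per_wall = 5,
                           orientation = "CW") {
  wells <- tidyr::expand_grid(region = regions_canonical,
                              idx = seq_len(n_well_electrodes)) |>
    dplyr::mutate(electrode_id = sprintf("%s_w%02d", .data$region, .data$idx)) |>
    dplyr::select("region", "electrode_id")
  tunnels <- tidyr::expand_grid(wall = walls_canonical,
                                idx = seq_len(n_tunnels_per_wall)) |>
    dplyr::mutate(
      tunnel_id = sprintf("%s_t%d", .data$wall, .data$idx),
      upstream_electrode = sprintf("%s_up", .data$tunnel_id),
      downstream_electrode = sprintf("%s_dn", .data$tunnel_id)) |>
    dplyr::select("tunnel_id", "wall", "upstream_electrode",
                  "downstream_electrode")
  mea_layout(wells, tunnels, orientation = orientation)
}

#' Read / write an array layout as JSON
#'
#' The JSON schema has top-level keys `electrode_spacing_mm`, `orientation`,
#' `wells` (object mapping sub-region to an array of electrode ids) and
#' `tunnels` (array of objects with `tunnel_id`, `wall`,
#' `upstream_electrode`, `downstream_electrode`). All layout invariants are
#' enforced on read; invalid layouts never reach the analysis stages.
#'
#' @param path File path.
#' @return `read_layout()` returns an [mea_layout()]; `write_layout()`
#'   returns `path` invisibly.
#' @export
read_layout <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  need <- c("wells", "tunnels")
  if (!all(need %in% names(raw))) {
    stop("layout JSON must contain keys: ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  wells <- purrr::imap(raw$wells, \(ids, region) {
    tibble::tibble(region = region, electrode_id = as.character(ids))
  }) |> purrr::list_rbind()
  tunnels <- tibble::as_tibble(raw$tunnels)
  mea_layout(wells, tunnels,
             electrode_spacing_mm = raw$electrode_spacing_mm %||% 0.2,
             orientation = raw$orientation %||% "CW")
}

#' @rdname read_layout
#' @param layout An `mea_layout`.
#' @export
write_layout <- function(layout, path) {
  stopifnot(inherits(layout, "mea_layout"))
  obj <- list(
    electrode_spacing_mm = layout$electrode_spacing_mm,
    orientation = layout$orientation,
    wells = split(layout$wells$electrode_id, layout$wells$region),
    tunnels = layout$tunnels)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' @export
print.mea_layout <- function(x, ...) {
  cat("<mea_layout> ", nrow(x$wells), " well electrodes in ",
      length(unique(x$wells$region)), " sub-regions; ",
      nrow(x$tunnels), " tunnels (", x$orientation, ", ",
      x$electrode_spacing_mm, " mm tunnel spacing)\n", sep = "")
  invisible(x)
}
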