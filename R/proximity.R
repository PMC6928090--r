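#' Bounding rectangle of the embedded protein
#'
#' `mode = "auto"` returns the tight x,y bounding rectangle of the frame's
#' protein atoms. `mode = "fixed"` returns a user rectangle: either the
#' full `c(x_min, x_max, y_min, y_max)` (atom positions ignored entirely)
#' or a dimension pair `c(width, height)` — by default the 30 x 40
#' Angstrom^2 rectangle — centred on the protein's mean x,y.
#'
#' @param frame A single-frame atom tibble.
#' @param mode `"auto"` or `"fixed"`.
#' @param rect For `"fixed"`: length-4 rectangle or length-2 dimensions.
#' @return A one-row tibble `x_min`, `x_max`, `y_min`, `y_max`.
#' @export
protein_bbox <- function(frame, mode = c("auto", "fixed"),
                         rect = c(30, 40)) {
  mode <- match.arg(mode)
  if (mode == "fixed" && length(rect) == 4) {
    return(tibble::tibble(x_min = rect[1], x_max = rect[2],
                          y_min = rect[3], y_max = rect[4]))
  }
  at <- dplyr::filter(frame, .data$role == "protein")
  if (nrow(at) == 0) abort("frame contains no protein atoms")
  if (mode == "auto") {
    tibble::tibble(x_min = min(at$x), x_max = max(at$x),
                   y_min = min(at$y), y_max = max(at$y))
  } else {
    cx <- mean(at$x); cy <- mean(at$y)
    tibble::tibble(x_min = cx - rect[1] / 2, x_max = cx + rect[1] / 2,
                   y_min = cy - rect[2] / 2, y_max = cy + rect[2] / 2)
  }
}

# 0-based cell-index ranges of the bbox snapped outward to whole cells
snap_bbox_cells <- function(bbox, grid) {
  x0 <- grid$origin[1]; y0 <- grid$origin[2]; s <- grid$spacing
  list(
    i_lo = floor((bbox$x_min - x0) / s),
    i_hi = ceiling((bbox$x_max - x0) / s) - 1,
    j_lo = floor((bbox$y_min - y0) / s),
    j_hi = ceiling((bbox$y_max - y0) / s) - 1
  )
}

# cells of the ring: snapped bbox expanded by margin_cells per side, minus
# the snapped bbox itself; indices wrapped periodically
ring_cells <- function(bbox, grid, margin_cells) {
  if (margin_cells < 1) abort("margin_cells must be at least 1")
  sn <- snap_bbox_cells(bbox, grid)
  outer <- tidyr::expand_grid(
    i = (sn$i_lo - margin_cells):(sn$i_hi + margin_cells),
    j = (sn$j_lo - margin_cells):(sn$j_hi + margin_cells)
  )
  inner <- outer$i >= sn$i_lo & outer$i <= sn$i_hi &
    outer$j >= sn$j_lo & outer$j <= sn$j_hi
  ring <- outer[!inner, , drop = FALSE]
  ring$i <- ((ring$i %% grid$nx) + grid$nx) %% grid$nx
  ring$j <- ((ring$j %% grid$ny) + grid$ny) %% grid$ny
  dplyr::distinct(ring)
}

#' Local membrane height in a cell ring around the protein
#'
#' The ring consists of the grid cells within `margin_cells` cells of the
#' protein's (snapped) bounding rectangle, excluding the rectangle's own
#' cells. The local height is by default the mean z over the *atoms* of
#' the chosen leaflet whose wrapped (x, y) falls in a ring cell — mirroring
#' the reference analysis, which averages head heavy atom heights rather
#' than cell means; `weight = "cells"` averages the ring's per-cell mean
#' heights instead.
#'
#' @param frame A single-frame atom tibble.
#' @param grid A [grid_spec()].
#' @param bbox Bounding rectangle from [protein_bbox()].
#' @param margin_cells Ring width in cells (default 5).
#' @param leaflet `"upper"` or `"lower"`.
#' @param weight `"atoms"` (default) or `"cells"`.
#' @return A one-row tibble: `local_height` (Angstrom), `ring_cells`
#'   (cells in the ring), `n_atoms`.
#' @export
local_ring_height <- function(frame, grid = grid_spec(), bbox,
                              margin_cells = 5,
                              leaflet = c("upper", "lower"),
                              weight = c("atoms", "cells")) {
  leaflet <- match.arg(leaflet)
  weight <- match.arg(weight)
  role <- role_for_leaflet(leaflet)
  ring <- ring_cells(bbox, grid, margin_cells)
  at <- dplyr::filter(frame, .data$role == .env$role)
  if (nrow(at) == 0) abort(paste0("no atoms of role ", role))
  at <- dplyr::mutate(
    at,
    i = cell_index(.data$x, grid$origin[1], grid$spacing, grid$nx),
    j = cell_index(.data$y, grid$origin[2], grid$spacing, grid$ny)
  )
  at <- dplyr::semi_join(at, ring, by = c("i", "j"))
  if (nrow(at) == 0) abort("ring region contains no head heavy atoms")
  h <- if (weight == "atoms") {
    mean(at$z)
  } else {
    cellmeans <- dplyr::summarise(dplyr::group_by(at, .data$i, .data$j),
                                  h = mean(.data$z), .groups = "drop")
    mean(cellmeans$h)
  }
  tibble::tibble(local_height = h, ring_cells = nrow(ring),
                 n_atoms = nrow(at))
}

#' Mass-weighted protein centre-of-mass height
#'
#' @param frame A single-frame atom tibble with `mass` and `role`.
#' @return COM z, Angstrom.
#' @export
protein_com_z <- function(frame) {
  at <- dplyr::filter(frame, .data$role == "protein")
  if (nrow(at) == 0) abort("frame contains no protein atoms")
  total <- sum(at$mass)
  if (!is.finite(total) || total <= 0) abort("protein has zero total mass")
  sum(at$mass * at$z) / total
}

#' Per-frame protein-proximity records
#'
#' For each frame: the protein bounding rectangle, the local ring height,
#' the global mean height of the leaflet's height map (mean over valid
#' cells), and the protein COM height. Note the deliberate asymmetry:
#' local height averages raw atom heights in the ring while global height
#' averages valid cell means.
#'
#' @param traj An `md_trajectory` containing protein atoms.
#' @param grid A [grid_spec()].
#' @param bbox_mode `"auto"` or `"fixed"` (see [protein_bbox()]).
#' @param rect Rectangle or dimensions for `"fixed"` mode.
#' @param margin_cells Ring width in cells.
#' @param leaflet Leaflet for local/global heights.
#' @return A `proximity_series` tibble: `frame`, `time`, `local_height`,
#'   `global_height`, `lift` (local - global), `com_z`, `ring_cells`,
#'   `x_min`, `x_max`, `y_min`, `y_max`. Use [glance()] for mean +/- SE.
#' @export
proximity_series <- function(traj, grid = grid_spec(),
                             bbox_mode = c("auto", "fixed"),
                             rect = c(30, 40), margin_cells = 5,
                             leaflet = c("upper", "lower")) {
  bbox_mode <- match.arg(bbox_mode)
  leaflet <- match.arg(leaflet)
  idx <- sort(unique(traj$frame))
  rows <- purrr::map(idx, function(f) {
    fr <- get_frame(traj, f)
    bb <- protein_bbox(fr, bbox_mode, rect)
    loc <- local_ring_height(fr, grid, bb, margin_cells, leaflet)
    hm <- build_height_map(fr, leaflet, grid)
    tibble::tibble(
      frame = f, time = fr$time[1],
      local_height = loc$local_height,
      global_height = global_mean_height(hm),
      lift = loc$local_height - global_mean_height(hm),
      com_z = protein_com_z(fr),
      ring_cells = loc$ring_cells,
      x_min = bb$x_min, x_max = bb$x_max,
      y_min = bb$y_min, y_max = bb$y_max
    )
  })
  out <- dplyr::bind_rows(rows)
  class(out) <- unique(c("proximity_series", class(out)))
  out
}

#' @describeIn proximity_series Mean and standard error over frames for
#'   the local height, global height, protein lift and COM height.
#' @param x A `proximity_series`.
#' @param ... Unused.
#' @method glance proximity_series
#' @export
glance.proximity_series <- function(x, ...) {
  tibble::tibble(
    n_frames = nrow(x),
    mean_local = mean(x$local_height), se_local = se_mean(x$local_height),
    mean_global = mean(x$global_height),
    se_global = se_mean(x$global_height),
    mean_lift = mean(x$lift), se_lift = se_mean(x$lift),
    mean_com_z = mean(x$com_z), se_com_z = se_mean(x$com_z)
  )
}

#' Extra deformation attributed to protein lift
#'
#' The difference between the time-mean local height near the protein and
#' the time-mean global membrane height: `local_mean - global_mean`.
#'
#' @param local_mean,global_mean Mean heights, Angstrom.
#' @return Lift contribution, Angstrom. Vectorized.
#' @export
lift_decomposition <- function(local_mean, global_mean) {
  local_mean - global_mean
}

#' Extra per-surface deformation attributed to flow
#'
#' Compares the time-mean deformation of a flow case with its stationary
#' counterpart. With `per_surface = TRUE` (default) the difference is
#' halved, attributing the extra corrugation equally to the top and bottom
#' extremes of the surface; `per_surface = FALSE` returns the raw
#' difference.
#'
#' @param deformation_flow,deformation_stationary Time-mean deformations,
#'   Angstrom.
#' @param per_surface Halve the difference (default `TRUE`).
#' @return Flow contribution, Angstrom. Vectorized.
#' @export
flow_decomposition <- function(deformation_flow, deformation_stationary,
                               per_surface = TRUE) {
  d <- deformation_flow - deformation_stationary
  if (per_surface) d / 2 else d
}
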