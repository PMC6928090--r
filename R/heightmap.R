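#' Grid specification for height-map rasterization
#'
#' The analysis rectangle is tiled by half-open square cells
#' `[x0 + i*spacing, x0 + (i+1)*spacing) x [y0 + j*spacing, y0 + (j+1)*spacing)`
#' with 0-based indices `i`, `j`. The default reproduces the 320 x 360
#' Angstrom^2 rectangle at 5 Angstrom spacing: 64 x 72 = 4608 cells.
#'
#' @param origin Lower-left corner `c(x0, y0)`, Angstrom.
#' @param spacing Cell edge length, Angstrom.
#' @param rect Rectangle dimensions `c(Lx, Ly)`, Angstrom; must be integer
#'   multiples of `spacing`.
#' @return A `grid_spec` list with fields `origin`, `spacing`, `nx`, `ny`,
#'   `rect`.
#' @export
grid_spec <- function(origin = c(0, 0), spacing = 5, rect = c(320, 360)) {
  if (spacing <= 0) abort("grid spacing must be positive")
  nx <- rect[1] / spacing
  ny <- rect[2] / spacing
  if (abs(nx - round(nx)) > 1e-9 || abs(ny - round(ny)) > 1e-9) {
    abort("rectangle dimensions must be integer multiples of the spacing")
  }
  structure(list(origin = as.numeric(origin), spacing = spacing,
                 nx = as.integer(round(nx)), ny = as.integer(round(ny)),
                 rect = as.numeric(rect)),
            class = "grid_spec")
}

#' @export
print.grid_spec <- function(x, ...) {
  cat(sprintf("<grid_spec> %d x %d cells of %g A over %g x %g A^2\n",
              x$nx, x$ny, x$spacing, x$rect[1], x$rect[2]))
  invisible(x)
}

role_for_leaflet <- function(leaflet) {
  switch(leaflet,
         upper = "upper_head_heavy",
         lower = "lower_head_heavy",
         abort("leaflet must be 'upper' or 'lower'"))
}

# wrapped cell indices (0-based) for atom coordinates on a grid
cell_index <- function(coord, origin, spacing, n) {
  w <- wrap_coord(coord - origin, n * spacing)
  i <- floor(w / spacing)
  # guard against floating-point landing exactly on the far edge
  as.integer(pmin(i, n - 1))
}

new_height_map <- function(df, grid, leaflet, time = NA_real_) {
  attr(df, "grid") <- grid
  attr(df, "leaflet") <- leaflet
  attr(df, "time") <- time
  class(df) <- unique(c("height_map", class(df)))
  df
}

#' Rasterize one frame's leaflet into a height map
#'
#' Each cell's height is the arithmetic mean z of the requested leaflet's
#' head heavy atoms whose wrapped (x, y) falls inside the half-open cell.
#' Cells containing no atoms are invalid and carry `NA` height (an explicit
#' mask; no sentinel values).
#'
#' @param frame A single-frame atom tibble (from [get_frame()]) with
#'   columns `x`, `y`, `z`, `role`.
#' @param leaflet `"upper"` or `"lower"`.
#' @param grid A [grid_spec()].
#' @return A `height_map` tibble with one row per cell: `i`, `j` (0-based),
#'   `h` (mean z, `NA` when invalid), `n_atoms`, `valid`; grid, leaflet and
#'   frame time carried as attributes.
#' @export
build_height_map <- function(frame, leaflet = c("upper", "lower"),
                             grid = grid_spec()) {
  leaflet <- match.arg(leaflet)
  role <- role_for_leaflet(leaflet)
  at <- dplyr::filter(frame, .data$role == .env$role)
  if (nrow(at) == 0) {
    abort(paste0("frame contains no atoms of role ", role))
  }
  at <- dplyr::mutate(
    at,
    i = cell_index(.data$x, grid$origin[1], grid$spacing, grid$nx),
    j = cell_index(.data$y, grid$origin[2], grid$spacing, grid$ny)
  )
  occ <- dplyr::summarise(
    dplyr::group_by(at, .data$i, .data$j),
    h = mean(.data$z), n_atoms = dplyr::n(), .groups = "drop"
  )
  full <- tidyr::expand_grid(i = 0:(grid$nx - 1L), j = 0:(grid$ny - 1L))
  out <- dplyr::left_join(full, occ, by = c("i", "j"))
  out <- dplyr::mutate(out,
                       n_atoms = dplyr::coalesce(.data$n_atoms, 0L),
                       valid = !is.na(.data$h))
  new_height_map(out, grid, leaflet,
                 time = attr(frame, "time", exact = TRUE) %||%
                   (if ("time" %in% names(frame)) frame$time[1] else NA_real_))
}

#' Height maps for every frame of a trajectory
#'
#' @param traj An `md_trajectory`.
#' @param leaflet `"upper"` or `"lower"`.
#' @param grid A [grid_spec()].
#' @return A `height_map_series` tibble: columns `frame`, `time`, `i`, `j`,
#'   `h`, `n_atoms`, `valid`; grid and leaflet as attributes.
#' @export
height_map_series <- function(traj, leaflet = c("upper", "lower"),
                              grid = grid_spec()) {
  leaflet <- match.arg(leaflet)
  idx <- sort(unique(traj$frame))
  maps <- purrr::map(idx, function(f) {
    fr <- get_frame(traj, f)
    hm <- build_height_map(fr, leaflet, grid)
    dplyr::mutate(hm, frame = f, time = fr$time[1], .before = 1)
  })
  out <- dplyr::bind_rows(maps)
  attr(out, "grid") <- grid
  attr(out, "leaflet") <- leaflet
  class(out) <- unique(c("height_map_series", class(out)))
  out
}

#' Number of valid cells of a height map
#' @param hm A `height_map` (or any tibble with a `valid` column).
#' @return Integer count.
#' @export
n_valid_cells <- function(hm) sum(hm$valid)

#' Global mean height of a height map
#'
#' Mean of the per-cell heights over valid cells only.
#'
#' @param hm A `height_map` tibble.
#' @return Mean height, Angstrom.
#' @export
global_mean_height <- function(hm) {
  h <- hm$h[hm$valid]
  if (length(h) == 0) abort("height map has no valid cells")
  mean(h)
}

#' Cellwise membrane thickness from two leaflet height maps
#'
#' Thickness is upper minus lower height where both cells are valid,
#' undefined (`NA`) elsewhere. Works on single maps or frame series built
#' on the same grid; series are joined by frame and cell.
#'
#' @param upper,lower Height maps (or series) on the same [grid_spec()].
#' @return A tibble with `i`, `j` (and `frame`, `time` for series),
#'   `thickness`, `valid`; attribute `mean_thickness` holds the average
#'   over jointly valid cells.
#' @export
local_thickness_map <- function(upper, lower) {
  gu <- attr(upper, "grid", exact = TRUE)
  gl <- attr(lower, "grid", exact = TRUE)
  if (!identical(gu[c("origin", "spacing", "nx", "ny")],
                 gl[c("origin", "spacing", "nx", "ny")])) {
    abort("upper and lower height maps use different grids")
  }
  keys <- intersect(c("frame", "time", "i", "j"), names(upper))
  u <- dplyr::select(upper, dplyr::all_of(keys), h_up = "h")
  l <- dplyr::select(lower, dplyr::all_of(setdiff(keys, "time")), h_lo = "h")
  out <- dplyr::left_join(u, l, by = setdiff(keys, "time"))
  out <- dplyr::mutate(out,
                       thickness = .data$h_up - .data$h_lo,
                       valid = !is.na(.data$thickness))
  out <- dplyr::select(out, -"h_up", -"h_lo")
  if (!any(out$valid)) abort("no jointly valid cells")
  attr(out, "grid") <- gu
  attr(out, "mean_thickness") <- mean(out$thickness[out$valid])
  out
}

#' Per-frame average membrane thickness
#'
#' @param upper,lower `height_map_series` for the two leaflets on the same
#'   grid.
#' @return A tibble with `frame`, `time`, `d` (mean thickness over jointly
#'   valid cells, Angstrom) and `n_cells`.
#' @export
thickness_series <- function(upper, lower) {
  tm <- local_thickness_map(upper, lower)
  if (!"frame" %in% names(tm)) abort("inputs must be frame series")
  dplyr::summarise(
    dplyr::group_by(tm, .data$frame, .data$time),
    d = mean(.data$thickness[.data$valid]),
    n_cells = sum(.data$valid), .groups = "drop"
  )
}

#' Export a height-map series as a long-format table
#'
#' @param hms A `height_map_series`.
#' @param path CSV destination.
#' @return Invisibly, `path`.
#' @export
write_height_maps <- function(hms, path) {
  readr::write_csv(
    dplyr::select(hms, "frame", "time", "i", "j", "h", "valid"), path
  )
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
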