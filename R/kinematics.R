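#' Mean leaflet velocity at a frame
#'
#' Average velocity component over one leaflet's head heavy atoms. The
#' default finite-difference mode differentiates the stored positions,
#' `(pos[t] - pos[t - dt]) / dt`, applying minimum-image unwrapping in the
#' periodic x, y dimensions so boundary crossings do not corrupt the
#' estimate. `method = "attached"` uses velocity columns attached with
#' [attach_velocities()].
#'
#' @param traj An `md_trajectory`.
#' @param leaflet `"upper"` or `"lower"`.
#' @param frame 1-based frame number; must be >= 2 in finite-difference
#'   mode.
#' @param component `"x"` or `"z"`.
#' @param method `"finite_difference"` or `"attached"`.
#' @return Mean velocity, Angstrom/ns.
#' @export
leaflet_velocity <- function(traj, leaflet = c("upper", "lower"), frame,
                             component = c("x", "z"),
                             method = c("finite_difference", "attached")) {
  leaflet <- match.arg(leaflet)
  component <- match.arg(component)
  method <- match.arg(method)
  role <- role_for_leaflet(leaflet)
  if (method == "attached") {
    vcol <- paste0("v", component)
    if (!vcol %in% names(traj)) abort("no velocities attached")
    fr <- dplyr::filter(traj, .data$frame == .env$frame,
                        .data$role == .env$role)
    if (nrow(fr) == 0) abort(paste0("no atoms of role ", role))
    if (anyNA(fr[[vcol]])) abort("attached velocities missing for atoms")
    return(mean(fr[[vcol]]))
  }
  if (frame < 2) {
    abort("finite-difference velocity needs frame >= 2 (no previous frame)")
  }
  disp <- leaflet_displacements(traj, role, frame)
  if (nrow(disp) == 0) abort(paste0("no atoms of role ", role))
  mean(disp[[paste0("d", component)]]) / traj_dt(traj)
}

# per-atom displacements frame-1 -> frame with minimum-image unwrapping
leaflet_displacements <- function(traj, role, frame) {
  box <- traj_box(traj)
  cur <- dplyr::filter(traj, .data$frame == .env$frame,
                       .data$role == .env$role)
  prev <- dplyr::filter(traj, .data$frame == .env$frame - 1L,
                        .data$role == .env$role)
  m <- dplyr::inner_join(
    dplyr::select(cur, "atom_id", "x", "y", "z"),
    dplyr::select(prev, "atom_id", xp = "x", yp = "y", zp = "z"),
    by = "atom_id"
  )
  dplyr::transmute(
    m,
    atom_id = .data$atom_id,
    dx = min_image(.data$x - .data$xp, box[1]),
    dy = min_image(.data$y - .data$yp, box[2]),
    dz = .data$z - .data$zp
  )
}

#' Shear strain rate from the inter-leaflet relative velocity
#'
#' The zx strain-rate component is the relative x-velocity between the two
#' leaflets divided by the membrane thickness:
#' `strain_rate = (v_upper_x - v_lower_x) / d`. The sign follows the
#' relative velocity.
#'
#' @param v_upper_x,v_lower_x Mean leaflet x-velocities, Angstrom/ns.
#' @param d Membrane thickness, Angstrom (> 0); 42 by default.
#' @return Strain rate, 1/ns. Vectorized over its arguments.
#' @export
strain_rate <- function(v_upper_x, v_lower_x, d = 42) {
  if (any(d <= 0)) abort("thickness d must be positive")
  (v_upper_x - v_lower_x) / d
}

#' Mean net x-force on the upper membrane surface at a frame
#'
#' Arithmetic mean of the attached per-atom x-force over the upper
#' leaflet's head heavy atoms.
#'
#' @param traj An `md_trajectory` with forces attached.
#' @param frame 1-based frame number.
#' @return Mean x-force, pN.
#' @export
net_force_x <- function(traj, frame) {
  if (!"fx" %in% names(traj)) abort("no forces attached to the trajectory")
  fr <- dplyr::filter(traj, .data$frame == .env$frame,
                      .data$role == "upper_head_heavy")
  if (nrow(fr) == 0) abort("no upper head heavy atoms at this frame")
  if (anyNA(fr$fx)) {
    abort(paste0("force missing for atom ", fr$atom_id[which(is.na(fr$fx))[1]],
                 " at frame ", frame))
  }
  mean(fr$fx)
}

#' Per-frame kinematics records
#'
#' For each frame after the first, estimates the mean x-velocity of each
#' leaflet (finite differences with periodic unwrapping, or attached
#' velocities), the relative velocity, the strain rate, the net x-force on
#' the upper surface (when forces are attached), and upper-leaflet
#' z-velocity diagnostics (signed mean and mean absolute value). Thickness
#' `d` is either the fixed constant (default 42 Angstrom) or the frame's
#' average local thickness computed from both leaflets' height maps.
#'
#' @param traj An `md_trajectory`.
#' @param d Fixed membrane thickness, Angstrom (used when
#'   `d_mode = "fixed"`).
#' @param d_mode `"fixed"` or `"per_frame"`.
#' @param grid [grid_spec()] used for per-frame thickness.
#' @param method Velocity estimation method, as in [leaflet_velocity()].
#' @return A `kinematics_series` tibble: `frame`, `time`, `v_x_upper`,
#'   `v_x_lower`, `v_x_rel`, `d`, `strain_rate`, `f_x_net`,
#'   `v_z_upper_signed`, `v_z_upper_abs`. Use [glance()] for mean +/- SE
#'   summaries.
#' @export
kinematics_series <- function(traj, d = 42,
                              d_mode = c("fixed", "per_frame"),
                              grid = grid_spec(),
                              method = c("finite_difference", "attached")) {
  d_mode <- match.arg(d_mode)
  method <- match.arg(method)
  nf <- n_frames(traj)
  if (nf < 2) abort("kinematics needs at least 2 frames")
  has_forces <- "fx" %in% names(traj)
  d_per_frame <- NULL
  if (d_mode == "per_frame") {
    up <- height_map_series(traj, "upper", grid)
    lo <- height_map_series(traj, "lower", grid)
    th <- thickness_series(up, lo)
    d_per_frame <- setNames(th$d, th$frame)
  }
  dt <- traj_dt(traj)
  rows <- purrr::map(2:nf, function(f) {
    du <- leaflet_displacements(traj, "upper_head_heavy", f)
    dl <- leaflet_displacements(traj, "lower_head_heavy", f)
    if (method == "attached") {
      vxu <- leaflet_velocity(traj, "upper", f, "x", method = "attached")
      vxl <- leaflet_velocity(traj, "lower", f, "x", method = "attached")
    } else {
      vxu <- mean(du$dx) / dt
      vxl <- mean(dl$dx) / dt
    }
    df <- if (d_mode == "fixed") d else unname(d_per_frame[as.character(f)])
    tibble::tibble(
      frame = f,
      time = (f - 1) * dt,
      v_x_upper = vxu, v_x_lower = vxl, v_x_rel = vxu - vxl,
      d = df,
      strain_rate = strain_rate(vxu, vxl, df),
      f_x_net = if (has_forces) net_force_x(traj, f) else NA_real_,
      v_z_upper_signed = mean(du$dz) / dt,
      v_z_upper_abs = mean(abs(du$dz)) / dt
    )
  })
  out <- dplyr::bind_rows(rows)
  class(out) <- unique(c("kinematics_series", class(out)))
  out
}

#' @describeIn kinematics_series Mean and standard error over frames for
#'   the strain rate, relative velocity, net force and thickness.
#' @param x A `kinematics_series`.
#' @param ... Unused.
#' @method glance kinematics_series
#' @export
glance.kinematics_series <- function(x, ...) {
  tibble::tibble(
    n_frames = nrow(x),
    mean_strain_rate = mean(x$strain_rate),
    se_strain_rate = se_mean(x$strain_rate),
    mean_v_x_rel = mean(x$v_x_rel),
    se_v_x_rel = se_mean(x$v_x_rel),
    mean_f_x_net = mean(x$f_x_net),
    se_f_x_net = se_mean(x$f_x_net),
    mean_d = mean(x$d)
  )
}
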