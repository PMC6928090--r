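#' An undulation mode for the synthetic bilayer surface
#'
#' The synthetic membrane surface is a sum of travelling cosine modes
#' `A * cos(kx*x + ky*y + phase + omega*t)` shared by both leaflets.
#'
#' @param amplitude Amplitude A in Angstrom.
#' @param wavevector `c(kx, ky)` in 1/Angstrom. For a surface that is
#'   periodic over the analysis rectangle choose wavelengths that divide
#'   the box lengths.
#' @param phase Phase offset, rad.
#' @param angular_speed Phase drift rate omega, rad/ns (a travelling wave).
#' @return A list describing the mode.
#' @export
surface_mode <- function(amplitude, wavevector, phase = 0,
                         angular_speed = 0) {
  stopifnot(amplitude >= 0, length(wavevector) == 2)
  list(amplitude = amplitude, wavevector = as.numeric(wavevector),
       phase = phase, angular_speed = angular_speed)
}

#' Parameters of the synthetic bilayer trajectory generator
#'
#' Defaults emulate the modelled system: a hexagonal membrane patch
#' (circumcircle diameter 179 Angstrom, flat sides parallel to the flow
#' axis) centred in a 320 x 360 Angstrom^2 periodic rectangle, two leaflets
#' 42 Angstrom apart, head-group pseudo-atoms at ~0.15 atoms/Angstrom^2 per
#' leaflet, gentle travelling undulations, an upper-leaflet drift of
#' 4.2 Angstrom/ns along x (flow), an embedded protein cylinder of radius
#' 12 Angstrom with a Gaussian membrane-lift bump, and frames every 0.1 ns.
#'
#' @param hex_circumdiameter Circumcircle diameter of the hexagonal patch,
#'   Angstrom.
#' @param rect Analysis rectangle `c(Lx, Ly)`, Angstrom; periodic in x, y.
#' @param thickness_d0 Unperturbed leaflet separation d0, Angstrom.
#' @param head_density Head heavy atoms per Angstrom^2 per leaflet.
#' @param modes List of [surface_mode()]s; `list()` for a flat surface.
#' @param noise_sigma SD of i.i.d. Gaussian z-noise per atom per frame,
#'   Angstrom.
#' @param drift_upper_x,drift_lower_x Leaflet drift velocities along x,
#'   Angstrom/ns (periodic wrapping).
#' @param protein List: `radius` (Angstrom), `height` (Angstrom),
#'   `n_atoms`, `com_z` (constant or `function(t)`, Angstrom). `NULL`
#'   omits the protein.
#' @param bump List `amplitude` (L, Angstrom) and `width` (w, Angstrom) of
#'   the upper-leaflet Gaussian lift `L*exp(-r^2/(2 w^2))` around the
#'   protein axis; `NULL` omits it.
#' @param force_mean_x,force_sigma Mean and SD of the i.i.d. Normal x-force
#'   assigned to each upper-leaflet head atom per frame, pN.
#' @param head_variant `"single"` (one P pseudo-atom per site) or
#'   `"cnp"` (a 3-atom C/N/P head per site).
#' @param dt Frame spacing, ns.
#' @param n_frames Number of frames.
#' @param seed RNG seed; fully determines the output.
#' @return A `synthetic_params` list.
#' @export
synthetic_params <- function(
    hex_circumdiameter = 179,
    rect = c(320, 360),
    thickness_d0 = 42,
    head_density = 0.15,
    modes = list(
      surface_mode(2.5, c(2 * pi / 80, 0), phase = 0.3, angular_speed = 0.9),
      surface_mode(1.5, c(0, 2 * pi / 90), phase = 1.1, angular_speed = 1.4)
    ),
    noise_sigma = 0.8,
    drift_upper_x = 4.2,
    drift_lower_x = 0,
    protein = list(radius = 12, height = 60, n_atoms = 200, com_z = 25),
    bump = list(amplitude = 4, width = 15),
    force_mean_x = 0.5,
    force_sigma = 0.2,
    head_variant = c("single", "cnp"),
    dt = 0.1,
    n_frames = 50,
    seed = 1L) {
  head_variant <- match.arg(head_variant)
  if (hex_circumdiameter > min(rect)) {
    abort("hexagon circumdiameter must fit inside the rectangle")
  }
  if (head_density <= 0 || noise_sigma < 0 || thickness_d0 <= 0 ||
      dt <= 0 || n_frames < 1) {
    abort("invalid synthetic parameters (densities/sigmas/sizes)")
  }
  structure(list(
    hex_circumdiameter = hex_circumdiameter, rect = as.numeric(rect),
    thickness_d0 = thickness_d0, head_density = head_density,
    modes = modes, noise_sigma = noise_sigma,
    drift_upper_x = drift_upper_x, drift_lower_x = drift_lower_x,
    protein = protein, bump = bump,
    force_mean_x = force_mean_x, force_sigma = force_sigma,
    head_variant = head_variant, dt = dt,
    n_frames = as.integer(n_frames), seed = as.integer(seed)
  ), class = "synthetic_params")
}

#' Point-in-hexagon test for the membrane patch
#'
#' Regular hexagon with flat sides parallel to the x axis, centred at
#' `center`, circumradius `R`.
#'
#' @param x,y Coordinates, Angstrom.
#' @param center `c(cx, cy)`.
#' @param R Circumradius, Angstrom.
#' @return Logical vector.
#' @export
in_hexagon <- function(x, y, center, R) {
  dx <- abs(x - center[1])
  dy <- abs(y - center[2])
  s3 <- sqrt(3)
  (dy <= s3 / 2 * R + 1e-9) & (s3 * dx + dy <= s3 * R + 1e-9)
}

#' Area of a regular hexagon with circumradius R
#' @param R Circumradius, Angstrom.
#' @return Area in Angstrom^2.
#' @export
hexagon_area <- function(R) 3 * sqrt(3) / 2 * R^2

# jittered square lattice clipped to the hexagon; returns tibble(x0, y0)
hex_lattice <- function(density, center, R, jitter_frac = 0.3) {
  a <- 1 / sqrt(density)
  xs <- seq(center[1] - R, center[1] + R, by = a)
  ys <- seq(center[2] - sqrt(3) / 2 * R, center[2] + sqrt(3) / 2 * R, by = a)
  g <- expand.grid(x0 = xs, y0 = ys)
  g$x0 <- g$x0 + runif(nrow(g), -jitter_frac * a, jitter_frac * a)
  g$y0 <- g$y0 + runif(nrow(g), -jitter_frac * a, jitter_frac * a)
  keep <- in_hexagon(g$x0, g$y0, center, R)
  tibble::as_tibble(g[keep, , drop = FALSE])
}

# expand lattice sites into head atoms (single P or 3-atom C/N/P head)
head_atoms_from_sites <- function(sites, variant) {
  if (variant == "single") {
    dplyr::mutate(sites, element = "P", dx = 0, dy = 0)
  } else {
    purrr::pmap_dfr(sites, function(x0, y0) {
      tibble::tibble(
        x0 = x0, y0 = y0,
        element = c("C", "N", "P"),
        dx = c(-1, 1, 0), dy = c(0.5, -0.5, 0)
      )
    })
  }
}

protein_layout <- function(protein) {
  n_levels <- 10L
  per <- max(1L, protein$n_atoms %/% n_levels)
  zs <- seq(-protein$height / 2, protein$height / 2, length.out = n_levels)
  purrr::map_dfr(seq_len(n_levels), function(l) {
    ang <- 2 * pi * (seq_len(per) - 1) / per + l * 0.37
    r <- protein$radius * ifelse(seq_len(per) %% 2 == 0, 1, 0.55)
    tibble::tibble(px = r * cos(ang), py = r * sin(ang), pz = zs[l])
  })
}

realize_com_z <- function(com_z, times) {
  if (is.function(com_z)) vapply(times, com_z, numeric(1))
  else rep(as.numeric(com_z), length(times))
}

surface_u <- function(x, y, t, modes) {
  u <- rep(0, length(x))
  for (m in modes) {
    u <- u + m$amplitude *
      cos(m$wavevector[1] * x + m$wavevector[2] * y + m$phase +
            m$angular_speed * t)
  }
  u
}

#' Generate a ground-truthed synthetic bilayer trajectory
#'
#' Lays head-group heavy atoms on a jittered lattice inside the hexagonal
#' patch on each leaflet, advects them with per-leaflet x-drift under
#' periodic wrapping, displaces them vertically by the shared undulation
#' field plus (upper leaflet only) a Gaussian lift bump around the protein
#' axis plus i.i.d. noise, fills a protein cylinder whose centre of mass
#' follows the prescribed z-trajectory, and draws i.i.d. Normal x-forces
#' for the upper head atoms. The dynamics are kinematic prescriptions
#' built for validation, not a physical simulation.
#'
#' @param params A [synthetic_params()] list.
#' @return A list with elements `trajectory` (an `md_trajectory` with
#'   force columns for upper head atoms), `topology` (the per-atom table),
#'   and `truth` (ground-truth record sufficient to recompute any expected
#'   statistic: initial positions, drifts, realized protein COM z, mode
#'   parameters, counts).
#' @export
generate_bilayer <- function(params = synthetic_params()) {
  stopifnot(inherits(params, "synthetic_params"))
  set.seed(params$seed)
  center <- params$rect / 2
  R <- params$hex_circumdiameter / 2
  up_sites <- hex_lattice(params$head_density, center, R)
  lo_sites <- hex_lattice(params$head_density, center, R)
  up <- head_atoms_from_sites(up_sites, params$head_variant)
  lo <- head_atoms_from_sites(lo_sites, params$head_variant)
  if (nrow(up) < 10 || nrow(lo) < 10) {
    abort("head_density too low: a leaflet has fewer than 10 atoms")
  }
  up$x0 <- up$x0 + up$dx; up$y0 <- up$y0 + up$dy
  lo$x0 <- lo$x0 + lo$dx; lo$y0 <- lo$y0 + lo$dy
  up$role <- "upper_head_heavy"; up$resname <- "UPL"; up$chain <- "U"
  lo$role <- "lower_head_heavy"; lo$resname <- "LOL"; lo$chain <- "L"

  prot <- NULL
  if (!is.null(params$protein)) {
    pl <- protein_layout(params$protein)
    prot <- tibble::tibble(
      x0 = center[1] + pl$px, y0 = center[2] + pl$py, element = "C",
      dx = 0, dy = 0, role = "protein", resname = "PRO", chain = "P",
      pz = pl$pz
    )
    # COM offset of the deterministic layout is removed so the realized
    # mass-weighted COM z equals the prescribed trajectory exactly
    prot$pz <- prot$pz - mean(prot$pz)
  }
  atoms <- dplyr::bind_rows(up, lo, if (!is.null(prot)) {
    dplyr::select(prot, -"pz")
  })
  atoms$atom_id <- seq_len(nrow(atoms))
  atoms$mass <- unname(element_masses[atoms$element])
  atoms$elety <- atoms$element
  atoms$segid <- NA_character_
  topology <- dplyr::select(
    tibble::as_tibble(atoms),
    "atom_id", "element", "mass", "role", "resname", "elety",
    "chain", "segid"
  )

  times <- (seq_len(params$n_frames) - 1) * params$dt
  com_z <- realize_com_z(
    if (is.null(params$protein)) 0 else params$protein$com_z, times
  )
  Lx <- params$rect[1]
  d0 <- params$thickness_d0
  n_up <- nrow(up); n_lo <- nrow(lo)
  n_pr <- if (is.null(prot)) 0L else nrow(prot)

  frames <- purrr::map(seq_along(times), function(i) {
    t <- times[i]
    xu_true <- up$x0 + params$drift_upper_x * t
    xl_true <- lo$x0 + params$drift_lower_x * t
    xu <- wrap_coord(xu_true, Lx)
    xl <- wrap_coord(xl_true, Lx)
    zu <- d0 / 2 + surface_u(xu, up$y0, t, params$modes)
    zl <- -d0 / 2 + surface_u(xl, lo$y0, t, params$modes)
    if (!is.null(params$bump) && !is.null(params$protein)) {
      rx <- min_image(xu - center[1], Lx)
      ry <- min_image(up$y0 - center[2], params$rect[2])
      zu <- zu + params$bump$amplitude *
        exp(-(rx^2 + ry^2) / (2 * params$bump$width^2))
    }
    if (params$noise_sigma > 0) {
      zu <- zu + rnorm(n_up, 0, params$noise_sigma)
      zl <- zl + rnorm(n_lo, 0, params$noise_sigma)
    }
    fx <- rnorm(n_up, params$force_mean_x, params$force_sigma)
    fr <- tibble::tibble(
      frame = i, time = t,
      atom_id = atoms$atom_id,
      x = c(xu, xl, if (n_pr > 0) prot$x0),
      y = c(up$y0, lo$y0, if (n_pr > 0) prot$y0),
      z = c(zu, zl, if (n_pr > 0) com_z[i] + prot$pz),
      fx = c(fx, rep(NA_real_, n_lo + n_pr)),
      fy = c(rep(0, n_up), rep(NA_real_, n_lo + n_pr)),
      fz = c(rep(0, n_up), rep(NA_real_, n_lo + n_pr))
    )
    fr
  })
  df <- dplyr::bind_rows(frames)
  df <- dplyr::left_join(
    df,
    dplyr::select(topology, "atom_id", "element", "mass", "role"),
    by = "atom_id"
  )
  df <- dplyr::select(df, "frame", "time", "atom_id", "element", "mass",
                      "role", "x", "y", "z", "fx", "fy", "fz")
  traj <- new_md_trajectory(df, box = params$rect, dt = params$dt)

  truth <- list(
    params = params,
    hex_circumradius = R, hex_area = hexagon_area(R), center = center,
    role_counts = table(topology$role),
    atoms0 = tibble::tibble(atom_id = atoms$atom_id, role = atoms$role,
                            x0 = atoms$x0, y0 = atoms$y0),
    drift = c(upper = params$drift_upper_x, lower = params$drift_lower_x),
    com_z = tibble::tibble(frame = seq_along(times), time = times,
                           com_z = com_z)
  )
  list(trajectory = traj, topology = topology, truth = truth)
}

#' Role map matching the synthetic fixture's residue names
#'
#' Fixtures written by [write_fixture()] use residue names `UPL`, `LOL`,
#' `PRO` for the upper leaflet, lower leaflet, and protein.
#'
#' @return A [role_map()].
#' @export
synthetic_role_map <- function() {
  role_map(
    upper_head_heavy = c(resname = "UPL"),
    lower_head_heavy = c(resname = "LOL"),
    protein = c(resname = "PRO")
  )
}

#' Write a synthetic trajectory as an on-disk fixture
#'
#' Writes `topology.pdb`, a multi-model PDB trajectory `traj.pdb`, a
#' long-format `forces.csv` (0-based `frame_index`), and the ground truth
#' as `truth.json`.
#'
#' @param traj,topology,truth Output of [generate_bilayer()].
#' @param outdir An existing writable directory.
#' @return Invisibly, a named character vector of the written paths.
#' @export
write_fixture <- function(traj, topology, truth, outdir) {
  if (!dir.exists(outdir)) {
    abort(paste0("output directory does not exist: ", outdir))
  }
  paths <- c(
    topology = file.path(outdir, "topology.pdb"),
    trajectory = file.path(outdir, "traj.pdb"),
    forces = file.path(outdir, "forces.csv"),
    truth = file.path(outdir, "truth.json")
  )
  f1 <- get_frame(traj, 1)
  f1 <- f1[order(f1$atom_id), ]
  resno <- ((topology$atom_id - 1) %% 9999) + 1
  bio3d::write.pdb(
    file = paths["topology"],
    xyz = as.vector(t(as.matrix(f1[, c("x", "y", "z")]))),
    resno = resno, resid = topology$resname, eleno = topology$atom_id,
    elety = topology$elety, chain = topology$chain
  )
  nf <- n_frames(traj)
  xyz <- matrix(NA_real_, nrow = nf, ncol = nrow(topology) * 3)
  for (i in seq_len(nf)) {
    fr <- get_frame(traj, i)
    fr <- fr[order(fr$atom_id), ]
    xyz[i, ] <- as.vector(t(as.matrix(fr[, c("x", "y", "z")])))
  }
  bio3d::write.pdb(
    file = paths["trajectory"], xyz = xyz,
    resno = resno, resid = topology$resname, eleno = topology$atom_id,
    elety = topology$elety, chain = topology$chain
  )
  ftab <- dplyr::filter(traj, !is.na(.data$fx))
  ftab <- dplyr::transmute(ftab, frame_index = .data$frame - 1L,
                           atom_id = .data$atom_id, fx = .data$fx,
                           fy = .data$fy, fz = .data$fz)
  readr::write_csv(ftab, paths["forces"])
  tr <- truth
  tr$params$modes <- purrr::map(tr$params$modes, unclass)
  tr$params$protein$com_z <- tr$com_z$com_z  # realized values, not closure
  tr$role_counts <- as.list(tr$role_counts)
  jsonlite::write_json(
    tr, paths["truth"], auto_unbox = TRUE, digits = NA, force = TRUE
  )
  invisible(paths)
}
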