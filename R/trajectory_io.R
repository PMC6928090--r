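#' Atomic masses for the elements found in lipid/protein heavy-atom models
#'
#' @noRd
element_masses <- c(
  H = 1.008, C = 12.011, N = 14.007, O = 15.999,
  P = 30.974, S = 32.06
)

#' Build a role map from selection rules
#'
#' A role map assigns each topology atom one of the four analysis roles:
#' `upper_head_heavy`, `lower_head_heavy`, `protein`, or `other`. Rules are
#' matched in order; the first rule an atom satisfies wins, and atoms
#' matching no rule get role `"other"`. Each rule may restrict residue name,
#' atom (element type) name, chain, and segment id; a field left `NA`
#' matches anything, and fields take comma-separated glob patterns
#' (e.g. `"P,N,C*"`).
#'
#' @param ... Named arguments, one per role, each a named character vector
#'   or list with any of the fields `resname`, `elety`, `chain`, `segid`.
#'   Names must be analysis roles. Repeating a role adds another rule.
#' @return A tibble with columns `role`, `resname`, `elety`, `chain`,
#'   `segid` (one row per rule), of class `role_map`.
#' @examples
#' role_map(
#'   upper_head_heavy = c(resname = "POPC", elety = "P,N,C*"),
#'   protein          = c(chain = "P")
#' )
#' @export
role_map <- function(...) {
  rules <- list(...)
  roles <- c("upper_head_heavy", "lower_head_heavy", "protein", "other")
  if (length(rules) > 0 &&
      (is.null(names(rules)) || any(!nzchar(names(rules))))) {
    abort("every role_map rule must be named by its role")
  }
  bad <- setdiff(names(rules), roles)
  if (length(bad) > 0) {
    abort(paste0("unknown role(s): ", paste(bad, collapse = ", ")))
  }
  fields <- c("resname", "elety", "chain", "segid")
  rows <- purrr::imap(rules, function(rule, role) {
    rule <- as.list(rule)
    extra <- setdiff(names(rule), fields)
    if (length(extra) > 0) {
      abort(paste0("unknown rule field(s): ", paste(extra, collapse = ", ")))
    }
    out <- as.list(setNames(rep(NA_character_, length(fields)), fields))
    out[names(rule)] <- vapply(rule, as.character, character(1))
    tibble::tibble(role = role, !!!out)
  })
  out <- dplyr::bind_rows(rows)
  if (nrow(out) == 0) {
    out <- tibble::tibble(
      role = character(), resname = character(), elety = character(),
      chain = character(), segid = character()
    )
  }
  class(out) <- c("role_map", class(out))
  out
}

# match one comma-separated glob pattern field against a character vector;
# NA pattern matches everything
match_field <- function(values, pattern) {
  if (is.na(pattern)) return(rep(TRUE, length(values)))
  pats <- trimws(strsplit(pattern, ",", fixed = TRUE)[[1]])
  hit <- rep(FALSE, length(values))
  for (p in pats) {
    hit <- hit | grepl(utils::glob2rx(p), values)
  }
  hit
}

apply_role_map <- function(atoms, rmap) {
  role <- rep("other", nrow(atoms))
  assigned <- rep(FALSE, nrow(atoms))
  for (r in seq_len(nrow(rmap))) {
    hit <- match_field(atoms$resname, rmap$resname[r]) &
      match_field(atoms$elety, rmap$elety[r]) &
      match_field(atoms$chain, rmap$chain[r]) &
      match_field(atoms$segid, rmap$segid[r])
    if (!any(hit)) {
      warn(paste0("role_map rule ", r, " (", rmap$role[r],
                  ") matched no atoms"))
    }
    take <- hit & !assigned
    role[take] <- rmap$role[r]
    assigned <- assigned | hit
  }
  role
}

infer_element <- function(elesy, elety) {
  el <- toupper(trimws(elesy))
  miss <- is.na(el) | el == ""
  # fall back to the first alphabetic character of the atom name
  el[miss] <- toupper(substr(gsub("[^A-Za-z].*$", "",
                                  trimws(elety[miss])), 1, 1))
  el
}

#' Read a PDB topology and assign analysis roles
#'
#' Reads atom records from a PDB file and labels each atom with one of the
#' four analysis roles via a [role_map()]. Element symbols come from the PDB
#' element column when present, otherwise from the atom name; masses come
#' from a standard element-mass table.
#'
#' @param path Path to a PDB file.
#' @param role_map A [role_map()]; the empty map labels every atom `"other"`.
#' @return A tibble with one row per atom: `atom_id`, `element`, `mass`,
#'   `role`, plus the PDB provenance columns `resname`, `elety`, `chain`,
#'   `segid`.
#' @export
read_topology <- function(path, role_map = memdeform::role_map()) {
  if (!file.exists(path)) abort(paste0("topology file not found: ", path))
  pdb <- tryCatch(
    bio3d::read.pdb(path, verbose = FALSE),
    error = function(e) abort(paste0("malformed PDB '", path, "': ",
                                     conditionMessage(e)))
  )
  a <- pdb$atom
  elesy <- if ("elesy" %in% names(a)) a$elesy else rep(NA_character_, nrow(a))
  atoms <- tibble::tibble(
    atom_id = as.integer(a$eleno),
    resname = as.character(a$resid),
    elety   = as.character(a$elety),
    chain   = as.character(a$chain),
    segid   = if ("segid" %in% names(a)) as.character(a$segid)
              else rep(NA_character_, nrow(a)),
    element = infer_element(elesy, a$elety)
  )
  atoms$mass <- unname(element_masses[atoms$element])
  if (anyNA(atoms$mass)) {
    unknown <- unique(atoms$element[is.na(atoms$mass)])
    abort(paste0("no mass known for element(s): ",
                 paste(unknown, collapse = ", ")))
  }
  atoms$role <- apply_role_map(atoms, role_map)
  dplyr::select(atoms, "atom_id", "element", "mass", "role",
                "resname", "elety", "chain", "segid")
}

new_md_trajectory <- function(df, box, dt) {
  attr(df, "box") <- box
  attr(df, "dt") <- dt
  class(df) <- unique(c("md_trajectory", class(df)))
  df
}

#' Box dimensions and sampling interval of a trajectory
#'
#' @param traj An `md_trajectory` tibble from [read_trajectory()] or
#'   [generate_bilayer()].
#' @return `traj_box()`: numeric `c(Lx, Ly)` in Angstrom. `traj_dt()`: the
#'   frame spacing in ns.
#' @export
traj_box <- function(traj) attr(traj, "box", exact = TRUE)

#' @rdname traj_box
#' @export
traj_dt <- function(traj) attr(traj, "dt", exact = TRUE)

#' Number of frames in a trajectory
#' @param traj An `md_trajectory`.
#' @return Integer frame count.
#' @export
n_frames <- function(traj) length(unique(traj$frame))

#' Extract one frame of a trajectory
#'
#' @param traj An `md_trajectory`.
#' @param index 1-based frame number.
#' @return A tibble of that frame's atoms with the box and time carried in
#'   attributes `box` and `time`.
#' @export
get_frame <- function(traj, index) {
  fr <- dplyr::filter(traj, .data$frame == index)
  if (nrow(fr) == 0) abort(paste0("no frame ", index, " in trajectory"))
  attr(fr, "box") <- traj_box(traj)
  attr(fr, "time") <- fr$time[1]
  fr
}

read_coords_pdb <- function(path, n_atoms) {
  pdb <- bio3d::read.pdb(path, multi = TRUE, verbose = FALSE)
  xyz <- pdb$xyz
  if (!is.matrix(xyz)) xyz <- matrix(xyz, nrow = 1)
  list(xyz = xyz, n_found = ncol(xyz) / 3)
}

read_coords_dcd <- function(path, n_atoms) {
  xyz <- bio3d::read.dcd(path, verbose = FALSE)
  if (!is.matrix(xyz)) xyz <- matrix(xyz, nrow = 1)
  list(xyz = xyz, n_found = ncol(xyz) / 3)
}

read_coords_csv <- function(path, n_atoms) {
  tab <- readr::read_csv(path, show_col_types = FALSE)
  need <- c("frame_index", "atom_id", "x", "y", "z")
  if (!all(need %in% names(tab))) {
    abort(paste0("coordinate CSV must have columns ",
                 paste(need, collapse = ", ")))
  }
  tab <- dplyr::arrange(tab, .data$frame_index, .data$atom_id)
  frames <- unique(tab$frame_index)
  n_found <- nrow(tab) / length(frames)
  xyz <- matrix(NA_real_, nrow = length(frames), ncol = n_found * 3)
  for (i in seq_along(frames)) {
    sub <- tab[tab$frame_index == frames[i], ]
    xyz[i, ] <- as.vector(t(as.matrix(sub[, c("x", "y", "z")])))
  }
  list(xyz = xyz, n_found = n_found)
}

#' Read a coordinate trajectory against a topology
#'
#' Supports DCD, multi-model PDB, and long-format CSV (columns
#' `frame_index`, `atom_id`, `x`, `y`, `z`; `frame_index` 0-based). Frames
#' are returned in file order with times `(i - 1) * dt` for the i-th frame.
#'
#' @param topology Atom table from [read_topology()].
#' @param path Trajectory file; format chosen by extension
#'   (`.dcd`, `.pdb`, `.csv`).
#' @param dt Sampling interval between stored frames, ns.
#' @param box Periodic rectangle `c(Lx, Ly)` in Angstrom (open in z).
#' @return An `md_trajectory`: a long tibble with columns `frame` (1-based),
#'   `time` (ns), `atom_id`, `element`, `mass`, `role`, `x`, `y`, `z`, and
#'   attributes `box` and `dt`.
#' @export
read_trajectory <- function(topology, path, dt = 0.1, box = c(320, 360)) {
  if (!file.exists(path)) abort(paste0("trajectory file not found: ", path))
  ext <- tolower(tools::file_ext(path))
  reader <- switch(ext,
    pdb = read_coords_pdb,
    dcd = read_coords_dcd,
    csv = read_coords_csv,
    abort(paste0("unsupported trajectory format: .", ext))
  )
  got <- reader(path, nrow(topology))
  if (got$n_found != nrow(topology)) {
    abort(paste0("atom-count mismatch: topology has ", nrow(topology),
                 " atoms but trajectory frames have ", got$n_found))
  }
  nf <- nrow(got$xyz)
  if (nf == 0) abort("trajectory contains zero frames")
  frames <- purrr::map(seq_len(nf), function(i) {
    m <- matrix(got$xyz[i, ], ncol = 3, byrow = TRUE)
    dplyr::mutate(topology,
      frame = i, time = (i - 1) * dt,
      x = m[, 1], y = m[, 2], z = m[, 3]
    )
  })
  df <- dplyr::bind_rows(frames)
  df <- dplyr::select(df, "frame", "time", "atom_id", "element", "mass",
                      "role", "x", "y", "z", dplyr::everything())
  new_md_trajectory(df, box = box, dt = dt)
}

# conversion from kcal mol^-1 A^-1 to pN
KCAL_MOL_A_TO_PN <- 69.4769

attach_vector_table <- function(traj, path, cols, units = "native") {
  tab <- if (is.data.frame(path)) tibble::as_tibble(path) else {
    if (!file.exists(path)) abort(paste0("table not found: ", path))
    readr::read_csv(path, show_col_types = FALSE)
  }
  need <- c("frame_index", "atom_id", cols)
  if (!all(need %in% names(tab))) {
    abort(paste0("table must have columns ", paste(need, collapse = ", ")))
  }
  nf <- n_frames(traj)
  bad <- tab$frame_index < 0 | tab$frame_index > nf - 1
  if (any(bad)) {
    abort(paste0("frame_index ", tab$frame_index[which(bad)[1]],
                 " out of range [0, ", nf - 1, "]"))
  }
  if (units == "kcal_mol_A") {
    tab[cols] <- lapply(tab[cols], function(v) v * KCAL_MOL_A_TO_PN)
  }
  tab$frame <- tab$frame_index + 1L
  box <- traj_box(traj); dt <- traj_dt(traj)
  out <- dplyr::left_join(
    traj, dplyr::select(tab, "frame", "atom_id", dplyr::all_of(cols)),
    by = c("frame", "atom_id")
  )
  new_md_trajectory(out, box = box, dt = dt)
}

#' Attach per-atom forces to a trajectory
#'
#' Reads a long-format force table (CSV columns `frame_index` 0-based,
#' `atom_id`, `fx`, `fy`, `fz`) and joins it onto the trajectory as columns
#' `fx`, `fy`, `fz`. Atoms without a force row carry `NA` (absent, not
#' zero-filled). Forces are stored in pN; set `units = "kcal_mol_A"` when
#' the source file holds kcal mol^-1 A^-1 gradients (converted at
#' 69.4769 pN per kcal mol^-1 A^-1).
#'
#' @param traj An `md_trajectory`.
#' @param path CSV file path, or a data frame with the same columns.
#' @param units `"pN"` (default, stored as-is) or `"kcal_mol_A"`.
#' @return The trajectory with force columns attached.
#' @export
attach_forces <- function(traj, path, units = c("pN", "kcal_mol_A")) {
  units <- match.arg(units)
  attach_vector_table(traj, path, c("fx", "fy", "fz"),
                      units = if (units == "pN") "native" else units)
}

#' Attach per-atom velocities to a trajectory
#'
#' Same table contract as [attach_forces()] with columns `vx`, `vy`, `vz`
#' in Angstrom/ns.
#'
#' @inheritParams attach_forces
#' @return The trajectory with velocity columns attached.
#' @export
attach_velocities <- function(traj, path) {
  attach_vector_table(traj, path, c("vx", "vy", "vz"))
}

#' Classify leaflets geometrically from the first frame
#'
#' Convenience classifier for topologies whose role labels do not encode
#' leaflet membership: atoms currently labelled with a head-heavy role are
#' re-labelled `upper_head_heavy`/`lower_head_heavy` by their position
#' relative to the bilayer mid-plane (mean head-atom z) at frame 1. Never
#' applied implicitly; call it only when membership is not fixed by
#' construction.
#'
#' @param traj An `md_trajectory` whose head atoms carry either head-heavy
#'   role.
#' @return The trajectory with per-atom leaflet roles reassigned.
#' @export
assign_leaflets_by_midplane <- function(traj) {
  f1 <- dplyr::filter(traj, .data$frame == 1,
                      .data$role %in% c("upper_head_heavy",
                                        "lower_head_heavy"))
  if (nrow(f1) == 0) abort("no head-heavy atoms to classify")
  mid <- mean(f1$z)
  upper_ids <- f1$atom_id[f1$z >= mid]
  box <- traj_box(traj); dt <- traj_dt(traj)
  out <- dplyr::mutate(traj, role = dplyr::case_when(
    .data$role %in% c("upper_head_heavy", "lower_head_heavy") &
      .data$atom_id %in% upper_ids ~ "upper_head_heavy",
    .data$role %in% c("upper_head_heavy", "lower_head_heavy") ~
      "lower_head_heavy",
    TRUE ~ .data$role
  ))
  new_md_trajectory(out, box = box, dt = dt)
}
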