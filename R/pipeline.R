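#' Read a pipeline configuration
#'
#' The configuration is a single YAML file (or an equivalent R list).
#' Analysis defaults follow the reference choices: 5 Angstrom grid over a
#' 320 x 360 Angstrom^2 rectangle, k = 5, category thresholds 4 and 8
#' Angstrom, fixed thickness d = 42 Angstrom, 0.1 ns sampling, 5-cell
#' proximity ring, auto protein bounding box — so a minimal config listing
#' only cases reproduces the standard analysis.
#'
#' Structure:
#' \preformatted{
#' output_dir: out
#' seed: 1
#' grid: {spacing: 5, rect: [320, 360]}
#' k: 5
#' thresholds: [4, 8]
#' d: 42
#' d_mode: fixed          # or per_frame
#' bbox: auto             # or [30, 40]
#' margin_cells: 5
#' dt: 0.1
#' cases:
#'   - label: "3_0.003"
#'     topology: topology.pdb
#'     trajectory: traj.pdb
#'     forces: forces.csv        # optional
#'     role_map:                 # optional; default: synthetic_role_map()
#'       upper_head_heavy: {resname: UPL}
#'       lower_head_heavy: {resname: LOL}
#'       protein: {resname: PRO}
#' }
#'
#' @param config Path to a YAML file, or a list with the same structure.
#' @return A validated `pipeline_config` list with defaults filled in.
#' @export
read_pipeline_config <- function(config) {
  cfg <- if (is.character(config)) yaml::read_yaml(config) else config
  defaults <- list(
    output_dir = "memdeform_report", seed = 1L,
    grid = list(spacing = 5, rect = c(320, 360)),
    k = 5L, thresholds = c(4, 8), d = 42, d_mode = "fixed",
    bbox = "auto", margin_cells = 5L, dt = 0.1
  )
  for (nm in names(defaults)) {
    if (is.null(cfg[[nm]])) cfg[[nm]] <- defaults[[nm]]
  }
  if (is.null(cfg$cases) || length(cfg$cases) == 0) {
    abort("config lists no cases")
  }
  labels <- vapply(cfg$cases, function(cs) as.character(cs$label),
                   character(1))
  if (anyDuplicated(labels)) abort("case labels must be unique")
  th <- unlist(cfg$thresholds)
  if (length(th) != 2 || any(th <= 0) || diff(th) <= 0) {
    abort("thresholds must be two strictly increasing positive values")
  }
  cfg$thresholds <- th
  cfg$grid_spec <- grid_spec(spacing = cfg$grid$spacing,
                             rect = unlist(cfg$grid$rect))
  structure(cfg, class = "pipeline_config")
}

config_role_map <- function(rm) {
  if (is.null(rm)) return(synthetic_role_map())
  args <- purrr::map(rm, function(fields) unlist(fields))
  do.call(role_map, args)
}

run_case <- function(cs, cfg, out_dir, log) {
  label <- as.character(cs$label)
  log(paste0("case ", label, ": reading ", cs$trajectory))
  topo <- read_topology(cs$topology, config_role_map(cs$role_map))
  traj <- read_trajectory(topo, cs$trajectory, dt = cfg$dt,
                          box = cfg$grid_spec$rect)
  if (!is.null(cs$forces)) traj <- attach_forces(traj, cs$forces)
  grid <- cfg$grid_spec
  prefix <- function(name) file.path(out_dir, paste0(label, "_", name))

  up <- height_map_series(traj, "upper", grid)
  lo <- height_map_series(traj, "lower", grid)
  write_height_maps(up, prefix("heights_upper.csv"))
  log(paste0("case ", label, ": ", n_frames(traj), " frames, ",
             sum(up$valid[up$frame == 1]), " valid cells in frame 1"))

  ds <- deformation_series(up, k = cfg$k)
  readr::write_csv(ds, prefix("deformation.csv"))
  cls <- classify_cells(up, thresholds = cfg$thresholds)
  readr::write_csv(category_tally(cls), prefix("categories.csv"))
  readr::write_csv(cumulative_category_distribution(cls),
                   prefix("category_distribution.csv"))

  kin <- NULL
  if (n_frames(traj) >= 2) {
    kin <- kinematics_series(traj, d = cfg$d, d_mode = cfg$d_mode,
                             grid = grid)
    readr::write_csv(kin, prefix("kinematics.csv"))
  }
  th <- thickness_series(up, lo)
  readr::write_csv(th, prefix("thickness.csv"))

  prox <- NULL
  if (any(traj$role == "protein")) {
    bbox_mode <- if (identical(cfg$bbox, "auto")) "auto" else "fixed"
    rect <- if (bbox_mode == "fixed") unlist(cfg$bbox) else c(30, 40)
    prox <- proximity_series(traj, grid, bbox_mode, rect,
                             cfg$margin_cells)
    readr::write_csv(prox, prefix("proximity.csv"))
  } else {
    log(paste0("case ", label, ": no protein atoms, skipping proximity"))
  }
  list(label = label, deformation = ds, classification = cls,
       kinematics = kin, thickness = th, proximity = prox)
}

#' Run the full analysis pipeline over a set of cases
#'
#' Executes, per case: trajectory reading, leaflet height maps, deformation
#' statistics, hill/valley classification, kinematics (when at least two
#' frames, forces optional), thickness, and protein proximity (when
#' protein atoms are present); then cross-case mean +/- SE summaries and
#' one-way ANOVA. All tables are written as CSV under the configured
#' output directory together with a run log recording parameters, package
#' version and seed. A failure in one case is logged and the remaining
#' cases still run.
#'
#' @param config Path to a YAML config or a list; see
#'   [read_pipeline_config()].
#' @return Invisibly, a list with per-case results (`cases`), the
#'   cross-case `summary` tibble, and `anova` results per metric.
#' @export
run_pipeline <- function(config) {
  cfg <- read_pipeline_config(config)
  out_dir <- cfg$output_dir
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  set.seed(cfg$seed)
  log_path <- file.path(out_dir, "run_log.txt")
  log_lines <- character(0)
  log <- function(msg) {
    line <- paste0(format(Sys.time(), "%H:%M:%S"), " ", msg)
    log_lines <<- c(log_lines, line)
    message(line)
  }
  log(paste0("memdeform ",
             as.character(utils::packageVersion("memdeform")),
             " | seed ", cfg$seed, " | grid ", cfg$grid_spec$spacing,
             " A | k ", cfg$k, " | thresholds ",
             paste(cfg$thresholds, collapse = "/"), " | d ", cfg$d,
             " (", cfg$d_mode, ")"))

  results <- list()
  for (cs in cfg$cases) {
    res <- tryCatch(
      run_case(cs, cfg, out_dir, log),
      error = function(e) {
        log(paste0("case ", cs$label, " FAILED: ", conditionMessage(e)))
        NULL
      }
    )
    if (!is.null(res)) results[[res$label]] <- res
  }

  summary_tbl <- NULL
  anovas <- list()
  if (length(results) >= 1) {
    metric_frames <- purrr::imap_dfr(results, function(res, label) {
      dplyr::bind_rows(
        tibble::tibble(case = label, metric = "deformation",
                       value = res$deformation$deformation),
        if (!is.null(res$kinematics)) tibble::tibble(
          case = label, metric = "strain_rate",
          value = res$kinematics$strain_rate
        ),
        if (!is.null(res$kinematics) &&
              !all(is.na(res$kinematics$f_x_net))) tibble::tibble(
          case = label, metric = "f_x_net",
          value = res$kinematics$f_x_net
        ),
        if (!is.null(res$proximity)) tibble::tibble(
          case = label, metric = "lift", value = res$proximity$lift
        ),
        if (!is.null(res$proximity)) tibble::tibble(
          case = label, metric = "com_z", value = res$proximity$com_z
        )
      )
    })
    summary_tbl <- dplyr::summarise(
      dplyr::group_by(metric_frames, .data$case, .data$metric),
      n = dplyr::n(), mean = mean(.data$value),
      se = se_mean(.data$value), .groups = "drop"
    )
    readr::write_csv(summary_tbl, file.path(out_dir, "summary.csv"))
    if (length(results) >= 2) {
      for (m in unique(metric_frames$metric)) {
        sub <- metric_frames[metric_frames$metric == m, ]
        if (length(unique(sub$case)) >= 2) {
          a <- anova_across_cases(sub, value, case)
          anovas[[m]] <- a
        }
      }
      if (length(anovas) > 0) {
        atab <- purrr::imap_dfr(anovas, function(a, m) {
          dplyr::mutate(glance(a), metric = m, .before = 1)
        })
        readr::write_csv(atab, file.path(out_dir, "anova.csv"))
        ptab <- purrr::imap_dfr(anovas, function(a, m) {
          dplyr::mutate(tidy(a), metric = m, .before = 1)
        })
        readr::write_csv(ptab, file.path(out_dir, "anova_pairwise.csv"))
      }
    }
  }
  log(paste0("done: ", length(results), "/", length(cfg$cases),
             " cases succeeded"))
  writeLines(log_lines, log_path)
  invisible(list(cases = results, summary = summary_tbl, anova = anovas,
                 config = cfg))
}
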