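# Shared fixture builders. Heavy synthetic trajectories are generated once
# per test run and cached.

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(name, expr) {
  if (is.null(.fixture_cache[[name]])) {
    assign(name, force(expr), envir = .fixture_cache)
  }
  .fixture_cache[[name]]
}

# perfectly flat, static bilayer: every upper head atom at +d0/2, lower at
# -d0/2; no protein unless supplied
params_flat <- function(n_frames = 3, density = 0.08, seed = 7, d0 = 42,
                        protein = NULL, bump = NULL) {
  synthetic_params(
    head_density = density, modes = list(), noise_sigma = 0,
    drift_upper_x = 0, drift_lower_x = 0, protein = protein, bump = bump,
    n_frames = n_frames, seed = seed, thickness_d0 = d0
  )
}

# drifting but otherwise flat bilayer for velocity/strain-rate recovery
params_drift <- function(v_upper = 4.2, v_lower = 0, n_frames = 10,
                         density = 0.05, noise = 0, seed = 11) {
  synthetic_params(
    head_density = density, modes = list(), noise_sigma = noise,
    drift_upper_x = v_upper, drift_lower_x = v_lower,
    protein = NULL, bump = NULL, n_frames = n_frames, seed = seed
  )
}

# single travelling undulation mode, noiseless, dense heads
params_one_mode <- function(A = 5, lambda = 80, n_frames = 10,
                            density = 0.3, seed = 13) {
  synthetic_params(
    head_density = density,
    modes = list(surface_mode(A, c(2 * pi / lambda, 0),
                              phase = 0.4, angular_speed = 2)),
    noise_sigma = 0, drift_upper_x = 0, drift_lower_x = 0,
    protein = NULL, bump = NULL, n_frames = n_frames, seed = seed
  )
}

# noise-dominated, flat-mean surface: the height distribution is
# time-invariant by construction
params_stationary <- function(n_frames = 30, density = 0.15, seed = 17) {
  synthetic_params(
    head_density = density, modes = list(), noise_sigma = 1.5,
    drift_upper_x = 0, drift_lower_x = 0, protein = NULL, bump = NULL,
    n_frames = n_frames, seed = seed
  )
}

flat_gen <- function() cached("flat", generate_bilayer(params_flat()))

default_gen <- function() {
  cached("default", generate_bilayer(synthetic_params(n_frames = 12,
                                                      seed = 101)))
}

# build a height_map tibble directly from a vector of heights (NA = invalid
# cell), bypassing rasterization — used to drive enumeration oracles
hm_from_heights <- function(h, nx = NULL, ny = NULL, spacing = 5) {
  n <- length(h)
  if (is.null(nx)) {
    nx <- max(1L, floor(sqrt(n)))
    ny <- ceiling(n / nx)
    length(h) <- nx * ny
  }
  grid <- grid_spec(spacing = spacing, rect = c(nx * spacing, ny * spacing))
  df <- tidyr::expand_grid(i = 0:(nx - 1L), j = 0:(ny - 1L))
  df$h <- h
  df$n_atoms <- ifelse(is.na(h), 0L, 1L)
  df$valid <- !is.na(h)
  attr(df, "grid") <- grid
  attr(df, "leaflet") <- "upper"
  class(df) <- unique(c("height_map", class(df)))
  df
}

# a single-frame atom tibble from raw columns
frame_from_atoms <- function(x, y, z, role, mass = 30.974, time = 0) {
  fr <- tibble::tibble(
    frame = 1L, time = time,
    atom_id = seq_along(x),
    element = "P", mass = mass, role = role,
    x = x, y = y, z = z
  )
  attr(fr, "time") <- time
  fr
}

# independent adjusted Fisher-Pearson skewness (oracle for the internal
# estimator; identical to e1071::skewness(type = 2))
skew_oracle <- function(x) {
  n <- length(x)
  g1 <- (sum((x - mean(x))^3) / n) / ((sum((x - mean(x))^2) / n)^1.5)
  g1 * sqrt(n * (n - 1)) / (n - 2)
}
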