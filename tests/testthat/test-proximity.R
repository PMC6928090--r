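test_that("bounding rectangles come from atoms in auto mode only", {
  fr <- frame_from_atoms(c(0, 30, 10), c(0, 20, 40), c(0, 5, 10),
                         "protein", mass = 12.011)
  bb <- protein_bbox(fr, "auto")
  expect_equal(unlist(bb), c(x_min = 0, x_max = 30, y_min = 0, y_max = 40))

  # an explicit fixed rectangle ignores atom positions entirely
  fixed <- protein_bbox(fr, "fixed", rect = c(100, 130, 200, 240))
  expect_equal(unlist(fixed),
               c(x_min = 100, x_max = 130, y_min = 200, y_max = 240))

  # dimension form centres the default 30 x 40 on the protein
  dim_bb <- protein_bbox(fr, "fixed", rect = c(30, 40))
  expect_equal(dim_bb$x_max - dim_bb$x_min, 30)
  expect_equal(dim_bb$y_max - dim_bb$y_min, 40)

  empty <- frame_from_atoms(1, 1, 1, "other")
  expect_error(protein_bbox(empty, "auto"), "no protein atoms")
})

test_that("the synthetic protein cylinder fits in the 30 x 40 rectangle", {
  g <- default_gen()
  fr <- get_frame(g$trajectory, 1)
  auto <- protein_bbox(fr, "auto")
  fixed <- protein_bbox(fr, "fixed", rect = c(30, 40))
  expect_gte(auto$x_min, fixed$x_min)
  expect_lte(auto$x_max, fixed$x_max)
  expect_gte(auto$y_min, fixed$y_min)
  expect_lte(auto$y_max, fixed$y_max)
})

test_that("protein COM height is the mass-weighted mean z", {
  two <- frame_from_atoms(c(0, 0), c(0, 0), c(0, 10), "protein", mass = 12)
  expect_equal(protein_com_z(two), 5)

  uneven <- frame_from_atoms(c(0, 0), c(0, 0), c(0, 13), "protein",
                             mass = c(12, 1))
  expect_equal(protein_com_z(uneven), 1)  # (12*0 + 1*13)/13

  g <- cached("sin_com", generate_bilayer(synthetic_params(
    head_density = 0.03, modes = list(), noise_sigma = 0,
    drift_upper_x = 0, drift_lower_x = 0, bump = NULL,
    protein = list(radius = 12, height = 60, n_atoms = 100,
                   com_z = function(t) 25 + sin(t)),
    n_frames = 10, seed = 43
  )))
  ps <- proximity_series(g$trajectory, margin_cells = 3)
  expect_equal(ps$com_z, g$truth$com_z$com_z, tolerance = 1e-9)
})

test_that("ring heights equal the flat surface away from any bump", {
  g <- cached("flat_prot", generate_bilayer(params_flat(
    protein = list(radius = 12, height = 60, n_atoms = 100, com_z = 25)
  )))
  fr <- get_frame(g$trajectory, 1)
  bb <- protein_bbox(fr, "auto")
  loc <- local_ring_height(fr, grid_spec(), bb, margin_cells = 5)
  expect_equal(loc$local_height, 21)
  expect_gte(loc$ring_cells, 1)
  expect_error(local_ring_height(fr, grid_spec(), bb, margin_cells = 0),
               "margin_cells")
})

test_that("ring height recovers the bump's ring-average by integration", {
  g <- cached("bump_dense", generate_bilayer(synthetic_params(
    head_density = 0.5, modes = list(), noise_sigma = 0,
    drift_upper_x = 0, drift_lower_x = 0,
    protein = list(radius = 12, height = 60, n_atoms = 100, com_z = 25),
    bump = list(amplitude = 4, width = 15),
    n_frames = 1, seed = 47
  )))
  fr <- get_frame(g$trajectory, 1)
  bb <- protein_bbox(fr, "auto")
  loc <- local_ring_height(fr, grid_spec(), bb, margin_cells = 5)

  # independent reconstruction of the ring region: snap the bbox outward
  # to 5 A cells, expand by 5 cells per side, subtract the snapped bbox
  s <- 5
  i_lo <- floor(bb$x_min / s); i_hi <- ceiling(bb$x_max / s) - 1
  j_lo <- floor(bb$y_min / s); j_hi <- ceiling(bb$y_max / s) - 1
  xs <- seq((i_lo - 5) * s + 0.125, (i_hi + 6) * s, by = 0.25)
  ys <- seq((j_lo - 5) * s + 0.125, (j_hi + 6) * s, by = 0.25)
  pts <- expand.grid(x = xs, y = ys)
  ci <- floor(pts$x / s); cj <- floor(pts$y / s)
  in_outer <- ci >= i_lo - 5 & ci <= i_hi + 5 & cj >= j_lo - 5 &
    cj <= j_hi + 5
  in_inner <- ci >= i_lo & ci <= i_hi & cj >= j_lo & cj <= j_hi
  ring_pts <- pts[in_outer & !in_inner, ]
  centre <- c(160, 180)
  r2 <- (ring_pts$x - centre[1])^2 + (ring_pts$y - centre[2])^2
  oracle <- 21 + mean(4 * exp(-r2 / (2 * 15^2)))

  expect_equal(loc$local_height, oracle, tolerance = 0.05)
})

test_that("atoms inside the bounding box never enter the local height", {
  g <- cached("flat_prot", generate_bilayer(params_flat(
    protein = list(radius = 12, height = 60, n_atoms = 100, com_z = 25)
  )))
  fr <- get_frame(g$trajectory, 1)
  bb <- protein_bbox(fr, "auto")
  base <- local_ring_height(fr, grid_spec(), bb, margin_cells = 5)
  # displace every head atom strictly inside the snapped bbox far upward
  s <- 5
  inside <- fr$role == "upper_head_heavy" &
    fr$x >= ceiling(bb$x_min / s) * s + s &
    fr$x < floor(bb$x_max / s) * s - s &
    fr$y >= ceiling(bb$y_min / s) * s + s &
    fr$y < floor(bb$y_max / s) * s - s
  moved <- fr
  moved$z[inside] <- 1000
  attr(moved, "time") <- attr(fr, "time")
  after <- local_ring_height(moved, grid_spec(), bb, margin_cells = 5)
  expect_equal(after$local_height, base$local_height)
})

test_that("proximity series match local/global with no bump or undulation", {
  g <- cached("flat_prot", generate_bilayer(params_flat(
    protein = list(radius = 12, height = 60, n_atoms = 100, com_z = 25)
  )))
  ps <- proximity_series(g$trajectory)
  expect_equal(ps$local_height, rep(21, 3))
  expect_equal(ps$global_height, rep(21, 3))
  expect_equal(ps$lift, rep(0, 3))
  s <- glance(ps)
  expect_equal(s$mean_com_z, 25)
})

test_that("decomposition arithmetic matches the worked discussion values", {
  expect_equal(lift_decomposition(26, 23.5), 2.5)
  expect_equal(lift_decomposition(10, 10), 0)
  expect_equal(lift_decomposition(23.5, 26), -lift_decomposition(26, 23.5))

  expect_equal(flow_decomposition(22.2, 19.5), 1.35)
  expect_lte(abs(flow_decomposition(22.2, 19.5) - 1.4), 0.05 + 1e-12)
  expect_equal(flow_decomposition(22.2, 19.5, per_surface = FALSE), 2.7)
  expect_equal(flow_decomposition(10, 10), 0)
  # affine in the first argument
  expect_equal(flow_decomposition(22.2 + 2, 19.5),
               flow_decomposition(22.2, 19.5) + 1)
})
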