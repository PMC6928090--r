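test_that("role maps partition atoms with first-match-wins semantics", {
  dir <- withr::local_tempdir()
  path <- file.path(dir, "three.pdb")
  bio3d::write.pdb(
    file = path,
    xyz = c(1, 1, 20, 2, 2, 21, 3, 3, -20),
    resno = 1:3, resid = c("POP", "POP", "TIP"), eleno = 1:3,
    elety = c("P", "C12", "OH2"), chain = "A"
  )
  topo <- read_topology(path, role_map(
    upper_head_heavy = c(resname = "POP", elety = "P,N,C*")
  ))
  expect_equal(topo$role, c("upper_head_heavy", "upper_head_heavy", "other"))
  expect_equal(topo$element, c("P", "C", "O"))
  expect_equal(topo$mass, c(30.974, 12.011, 15.999))

  # empty map is a vacuous match; roles still partition the atom set
  all_other <- read_topology(path, role_map())
  expect_true(all(all_other$role == "other"))
  expect_equal(nrow(all_other), 3)

  # a rule matching nothing warns but does not error
  expect_warning(
    read_topology(path, role_map(protein = c(resname = "XXX"))),
    "matched no atoms"
  )
})

test_that("synthetic fixture round-trips through PDB within format precision", {
  g <- cached("io_small", generate_bilayer(synthetic_params(
    head_density = 0.03, n_frames = 5, seed = 5,
    protein = list(radius = 12, height = 60, n_atoms = 50, com_z = 25)
  )))
  dir <- withr::local_tempdir()
  paths <- write_fixture(g$trajectory, g$topology, g$truth, dir)
  expect_true(all(file.exists(paths)))

  topo <- read_topology(paths["topology"], synthetic_role_map())
  expect_equal(as.integer(table(topo$role)[names(g$truth$role_counts)]),
               as.integer(g$truth$role_counts))

  traj <- read_trajectory(topo, paths["trajectory"], dt = 0.1)
  expect_equal(n_frames(traj), 5)
  expect_equal(sort(unique(traj$time)), c(0, 0.1, 0.2, 0.3, 0.4))
  ord <- order(g$trajectory$frame, g$trajectory$atom_id)
  ord2 <- order(traj$frame, traj$atom_id)
  expect_lt(max(abs(traj$x[ord2] - g$trajectory$x[ord])), 1e-3)
  expect_lt(max(abs(traj$z[ord2] - g$trajectory$z[ord])), 1e-3)

  # re-reading is idempotent
  again <- read_trajectory(topo, paths["trajectory"], dt = 0.1)
  expect_identical(traj, again)

  # forces round-trip through the CSV table
  with_f <- attach_forces(traj, paths["forces"])
  a <- dplyr::filter(with_f, role == "upper_head_heavy")
  b <- dplyr::filter(g$trajectory, role == "upper_head_heavy")
  expect_equal(
    a$fx[order(a$frame, a$atom_id)],
    b$fx[order(b$frame, b$atom_id)],
    tolerance = 1e-12
  )
  # lower-leaflet atoms have no force rows: absent, not zero
  expect_true(all(is.na(
    dplyr::filter(with_f, role == "lower_head_heavy")$fx
  )))
})

test_that("trajectory and force readers reject inconsistent inputs", {
  g <- cached("io_small", generate_bilayer(synthetic_params(
    head_density = 0.03, n_frames = 5, seed = 5,
    protein = list(radius = 12, height = 60, n_atoms = 50, com_z = 25)
  )))
  dir <- withr::local_tempdir()
  paths <- write_fixture(g$trajectory, g$topology, g$truth, dir)
  topo <- read_topology(paths["topology"], synthetic_role_map())

  expect_error(read_trajectory(topo[1:10, ], paths["trajectory"]),
               "atom-count mismatch")
  expect_error(read_trajectory(topo, file.path(dir, "nope.pdb")),
               "not found")

  traj <- read_trajectory(topo, paths["trajectory"], dt = 0.1)
  expect_error(
    attach_forces(traj, tibble::tibble(frame_index = 99, atom_id = 1,
                                       fx = 1, fy = 0, fz = 0)),
    "out of range"
  )
})

test_that("single force rows land on the right frame and atom, with units", {
  g <- flat_gen()
  traj <- dplyr::select(g$trajectory, -fx, -fy, -fz)
  traj <- memdeform:::new_md_trajectory(traj, traj_box(g$trajectory),
                                        traj_dt(g$trajectory))
  one <- tibble::tibble(frame_index = 0, atom_id = 7, fx = 1.0,
                        fy = 0, fz = 0)
  with_f <- attach_forces(traj, one)
  hit <- dplyr::filter(with_f, frame == 1, atom_id == 7)
  expect_equal(hit$fx, 1.0)
  expect_true(all(is.na(dplyr::filter(with_f, atom_id != 7)$fx)))

  # kcal/mol/A inputs are converted to pN
  conv <- attach_forces(traj, one, units = "kcal_mol_A")
  expect_equal(dplyr::filter(conv, frame == 1, atom_id == 7)$fx,
               69.4769, tolerance = 1e-6)
})

test_that("trajectory CSV coordinate tables are a supported format", {
  g <- flat_gen()
  traj <- g$trajectory
  dir <- withr::local_tempdir()
  csv <- file.path(dir, "coords.csv")
  readr::write_csv(
    dplyr::transmute(traj, frame_index = frame - 1L, atom_id, x, y, z),
    csv
  )
  topo <- g$topology
  back <- read_trajectory(topo, csv, dt = 0.1)
  ord <- order(traj$frame, traj$atom_id)
  ord2 <- order(back$frame, back$atom_id)
  expect_equal(back$z[ord2], traj$z[ord], tolerance = 1e-9)
})

test_that("midplane leaflet classifier splits a bilayer geometrically", {
  g <- flat_gen()
  scrambled <- dplyr::mutate(
    g$trajectory,
    role = ifelse(role %in% c("upper_head_heavy", "lower_head_heavy"),
                  "upper_head_heavy", role)
  )
  scrambled <- memdeform:::new_md_trajectory(scrambled,
                                             traj_box(g$trajectory),
                                             traj_dt(g$trajectory))
  fixed <- assign_leaflets_by_midplane(scrambled)
  expect_equal(
    dplyr::arrange(fixed, frame, atom_id)$role,
    dplyr::arrange(g$trajectory, frame, atom_id)$role
  )
})
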