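test_that("center of mass is the mass-weighted mean", {
  xyz <- rbind(c(0, 0, 0), c(2, 0, 0), c(0, 4, 0))
  g <- atom_group(1:2, c(1, 1))
  expect_equal(center_of_mass(g, xyz), c(1, 0, 0))
  expect_equal(center_of_mass(atom_group(3, 5), xyz), c(0, 4, 0))
  g13 <- atom_group(c(1, 2), c(1, 3))
  xyz2 <- rbind(c(0, 0, 0), c(4, 0, 0))
  expect_equal(center_of_mass(g13, xyz2), c(3, 0, 0))
  expect_error(atom_group(integer(0), 1), "empty")
})

test_that("major inertia axis finds the long axis with a fixed sign", {
  # rod along z
  xyz <- cbind(0, 0, seq(-5, 5, length.out = 7))
  g <- atom_group(1:7, 1)
  ax <- major_inertia_axis(g, xyz, c(1, 7))   # reference points +z
  expect_equal(ax, c(0, 0, 1), tolerance = 1e-10)
  ax2 <- major_inertia_axis(g, xyz, c(7, 1))  # flipped reference
  expect_equal(ax2, c(0, 0, -1), tolerance = 1e-10)
  # toy quadruplex: stacking axis equals the symmetry axis
  sys <- quad_system()
  ax3 <- major_inertia_axis(sys$groups$quadruplex, sys$xyz,
                            sys$orientation_ref)
  expect_lt(sqrt(sum((abs(ax3) - c(0, 0, 1))^2)), 1e-6)
  expect_equal(ax3[3], 1, tolerance = 1e-6)  # oriented 5' -> 3' (+z)
  # spherical top: regular tetrahedron
  tet <- rbind(c(1, 1, 1), c(1, -1, -1), c(-1, 1, -1), c(-1, -1, 1))
  expect_error(major_inertia_axis(atom_group(1:4, 1), tet, c(1, 2)),
               class = "wtmetad_degeneracy_error")
})

test_that("com distance is symmetric and sees symmetric sites as equal", {
  xyz <- rbind(c(0, 0, 0), c(3, 4, 0))
  a <- atom_group(1, 1); b <- atom_group(2, 1)
  expect_equal(com_distance(a, b, xyz), 5)
  expect_equal(com_distance(b, a, xyz), 5)
  expect_equal(com_distance(a, a, xyz), 0)
  # ligand at a site vs the 90-degree-rotated site: identical d
  quad <- build_toy_quadruplex(6, 3.4, 8)
  lig1 <- rigid_ligand(position = c(6.5, 0.5, 1.2),
                       orientation = c(1.0, 0.4))
  sys1 <- assemble_system(quad, lig1)
  d1 <- com_distance(sys1$groups$quadruplex, sys1$groups$scaffold, sys1$xyz)
  xyz2 <- sys1$xyz
  xyz2[25:26, ] <- rotate_about_z(sys1$xyz[25:26, ], pi / 2)
  d2 <- com_distance(sys1$groups$quadruplex, sys1$groups$scaffold, xyz2)
  expect_equal(d1, d2, tolerance = 1e-8)
})

test_that("axis torsion reproduces the four-point dihedral", {
  # two rods: parallel axes perpendicular to the COM-COM vector
  rod <- function(center, dir, n = 5, half = 3) {
    t(sapply(seq(-half, half, length.out = n), function(s) center + s * dir))
  }
  xyz <- rbind(rod(c(0, 0, 0), c(0, 0, 1)), rod(c(8, 0, 0), c(0, 0, 1)))
  g1 <- atom_group(1:5, 1); g2 <- atom_group(6:10, 1)
  expect_equal(axis_torsion(g1, g2, xyz, c(1, 5), c(6, 10)), 0,
               tolerance = 1e-10)
  # antiparallel axes -> pi
  xyz2 <- rbind(rod(c(0, 0, 0), c(0, 0, 1)), rod(c(8, 0, 0), c(0, 0, 1)))
  tors <- axis_torsion(g1, g2, xyz2, c(1, 5), c(10, 6))
  expect_equal(abs(tors), pi, tolerance = 1e-10)
  # second axis rotated 90 degrees about the COM-COM vector (x)
  xyz3 <- rbind(rod(c(0, 0, 0), c(0, 0, 1)), rod(c(8, 0, 0), c(0, 1, 0)))
  tor3 <- axis_torsion(g1, g2, xyz3, c(1, 5), c(6, 10))
  expect_equal(abs(tor3), pi / 2, tolerance = 1e-10)
  # brute-force oracle on the same four points
  a1 <- major_inertia_axis(g1, xyz3, c(1, 5))
  a2 <- major_inertia_axis(g2, xyz3, c(6, 10))
  c1 <- center_of_mass(g1, xyz3); c2 <- center_of_mass(g2, xyz3)
  expect_equal(tor3, dihedral_brute(c1 + a1, c1, c2, c2 + a2),
               tolerance = 1e-10)
  # coincident COMs are rejected
  xyz4 <- rbind(rod(c(0, 0, 0), c(0, 0, 1)), rod(c(0, 0, 0), c(0, 1, 0)))
  expect_error(axis_torsion(g1, g2, xyz4, c(1, 5), c(6, 10)), "coincide")
})

test_that("POA and DFA decompose the COM offset orthogonally", {
  sys <- quad_system()
  qg <- sys$groups$quadruplex
  ref <- sys$orientation_ref
  # scaffold on the receptor COM -> POA 0
  at_com <- assemble_system(build_toy_quadruplex(6),
                            rigid_ligand(position = c(0, 0, 0)))
  # move the scaffold exactly to the receptor COM
  com_q <- center_of_mass(at_com$groups$quadruplex, at_com$xyz)
  at_com$xyz[25, ] <- com_q
  expect_equal(projection_on_axis(at_com$groups$scaffold,
                                  at_com$groups$quadruplex, at_com$xyz,
                                  at_com$orientation_ref), 0,
               tolerance = 1e-10)
  # +5 A along the oriented axis -> +5; perpendicular offset -> POA 0
  ax <- major_inertia_axis(qg, sys$xyz, ref)
  xyz5 <- sys$xyz
  xyz5[25, ] <- center_of_mass(qg, sys$xyz) + 5 * ax
  expect_equal(projection_on_axis(sys$groups$scaffold, qg, xyz5, ref), 5,
               tolerance = 1e-10)
  expect_equal(distance_from_axis(sys$groups$scaffold, qg, xyz5, ref), 0,
               tolerance = 1e-8)
  perp <- c(ax[3], 0, -ax[1]); perp <- perp / sqrt(sum(perp^2))
  xyz7 <- sys$xyz
  xyz7[25, ] <- center_of_mass(qg, sys$xyz) + 7 * perp
  expect_equal(distance_from_axis(sys$groups$scaffold, qg, xyz7, ref), 7,
               tolerance = 1e-8)
  expect_equal(projection_on_axis(sys$groups$scaffold, qg, xyz7, ref), 0,
               tolerance = 1e-8)
})

test_that("POA^2 + DFA^2 equals the squared COM offset (100 seeds)", {
  quad <- build_toy_quadruplex(6)
  for (s in 1:100) {
    set.seed(s)
    lig <- rigid_ligand(position = rnorm(3, sd = 6),
                        orientation = runif(2, -pi, pi))
    sys <- assemble_system(quad, lig)
    poa <- projection_on_axis(sys$groups$scaffold, sys$groups$quadruplex,
                              sys$xyz, sys$orientation_ref)
    dfa <- distance_from_axis(sys$groups$scaffold, sys$groups$quadruplex,
                              sys$xyz, sys$orientation_ref)
    delta <- center_of_mass(sys$groups$scaffold, sys$xyz) -
      center_of_mass(sys$groups$quadruplex, sys$xyz)
    expect_lt(abs(poa^2 + dfa^2 - sum(delta^2)), 1e-10)
  }
})

test_that("all CVs are invariant under global rigid motions", {
  sys <- quad_system()
  specs <- list(
    cv_spec("com_distance", list(sys$groups$quadruplex,
                                 sys$groups$scaffold)),
    cv_spec("projection_on_axis", list(sys$groups$scaffold,
                                       sys$groups$quadruplex),
            orientation_ref = sys$orientation_ref),
    cv_spec("distance_from_axis", list(sys$groups$scaffold,
                                       sys$groups$quadruplex),
            orientation_ref = sys$orientation_ref),
    cv_spec("axis_torsion", list(sys$groups$ligand, sys$groups$quadruplex),
            orientation_ref = list(c(25, 26), sys$orientation_ref)))
  base <- vapply(specs, evaluate_cv, numeric(1), xyz = sys$xyz)
  for (s in 1:10) {
    mot <- random_rigid_motion(s)
    moved <- apply_rigid(sys$xyz, mot)
    v <- vapply(specs, evaluate_cv, numeric(1), xyz = moved)
    dv <- v - base
    dv[4] <- dv[4] - 2 * pi * round(dv[4] / (2 * pi))
    expect_lt(max(abs(dv)), 1e-8)
  }
})

test_that("d, POA, DFA are blind to the receptor's 4-fold symmetry", {
  quad <- build_toy_quadruplex(6, 3.4, 8)
  lig <- rigid_ligand(position = c(6.5, 1.5, -2.3),
                      orientation = c(0.8, 0.3))
  sys <- assemble_system(quad, lig)
  vals1 <- c(
    com_distance(sys$groups$quadruplex, sys$groups$scaffold, sys$xyz),
    projection_on_axis(sys$groups$scaffold, sys$groups$quadruplex,
                       sys$xyz, sys$orientation_ref),
    distance_from_axis(sys$groups$scaffold, sys$groups$quadruplex,
                       sys$xyz, sys$orientation_ref))
  for (k in 1:3) {
    xyz_r <- sys$xyz
    xyz_r[25:26, ] <- rotate_about_z(sys$xyz[25:26, ], k * pi / 2)
    vals2 <- c(
      com_distance(sys$groups$quadruplex, sys$groups$scaffold, xyz_r),
      projection_on_axis(sys$groups$scaffold, sys$groups$quadruplex,
                         xyz_r, sys$orientation_ref),
      distance_from_axis(sys$groups$scaffold, sys$groups$quadruplex,
                         xyz_r, sys$orientation_ref))
    expect_lt(max(abs(vals1 - vals2)), 1e-8)
  }
})

test_that("oriented axis does not flip along a slow rotation", {
  xyz0 <- cbind(0, 0, seq(-5, 5, length.out = 9))
  g <- atom_group(1:9, 1)
  prev <- major_inertia_axis(g, xyz0, c(1, 9))
  for (ang in seq(0.05, 2 * pi, by = 0.05)) {   # ~3 degrees per frame
    R <- matrix(c(cos(ang), 0, sin(ang), 0, 1, 0,
                  -sin(ang), 0, cos(ang)), 3, 3)
    ax <- major_inertia_axis(g, xyz0 %*% R, c(1, 9))
    expect_gt(sum(ax * prev), 0)   # never jumps by more than 90 degrees
    prev <- ax
  }
})

test_that("wall restraint is half-harmonic with a continuous derivative", {
  w <- wall_spec("d", limit = 27, k = 10)
  expect_equal(wall_energy(20, w)$energy, 0)
  expect_equal(wall_energy(27, w)$energy, 0)
  expect_equal(wall_energy(27, w)$derivative, 0)
  expect_equal(wall_energy(28, w)$energy, 10)
  expect_equal(wall_energy(28, w)$derivative, 20)
  expect_error(wall_spec("d", limit = -1), "positive")
})

test_that("finite-difference CV gradients match analytic formulas", {
  sys <- quad_system()
  spec_d <- cv_spec("com_distance", list(sys$groups$quadruplex,
                                         sys$groups$scaffold))
  g <- cv_gradient(spec_d, sys$xyz)
  # analytic: unit vector between COMs, mass-apportioned within groups
  c1 <- center_of_mass(sys$groups$quadruplex, sys$xyz)
  c2 <- center_of_mass(sys$groups$scaffold, sys$xyz)
  u <- (c2 - c1) / sqrt(sum((c2 - c1)^2))
  m <- sys$groups$quadruplex$masses / sum(sys$groups$quadruplex$masses)
  for (j in seq_along(sys$groups$quadruplex$indices)) {
    i <- sys$groups$quadruplex$indices[j]
    expect_equal(g[i, ], -u * m[j], tolerance = 1e-6)
  }
  expect_equal(g[25, ], u, tolerance = 1e-6)
  # rigid translation of everything leaves d unchanged
  expect_lt(max(abs(colSums(g))), 1e-8)
  # POA gradient for the single-bead point group equals the oriented axis
  spec_poa <- cv_spec("projection_on_axis",
                      list(sys$groups$scaffold, sys$groups$quadruplex),
                      orientation_ref = sys$orientation_ref)
  gp <- cv_gradient(spec_poa, sys$xyz)
  ax <- major_inertia_axis(sys$groups$quadruplex, sys$xyz,
                           sys$orientation_ref)
  expect_equal(gp[25, ], ax, tolerance = 1e-6)
})
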