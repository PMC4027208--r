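#' Atom group
#'
#' A named selection of beads with masses, the building block of every
#' geometric collective variable (e.g. the receptor, the ligand scaffold
#' whose center of mass is tracked, or the tail whose inertia axis enters
#' the psi torsion).
#'
#' @param indices bead indices into the system coordinate matrix.
#' @param masses per-member masses (amu), recycled if scalar.
#' @param label human-readable group name.
#' @return Object of class `atom_group`.
#' @export
atom_group <- function(indices, masses, label = "group") {
  indices <- as.integer(indices)
  if (length(indices) == 0L) stop_param("atom group '", label, "' is empty")
  masses <- rep_len(as.numeric(masses), length(indices))
  if (any(!is.finite(masses)) || any(masses <= 0))
    stop_param("atom group '", label, "' has non-positive masses")
  structure(list(indices = indices, masses = masses, label = label),
            class = "atom_group")
}

group_xyz <- function(group, xyz) {
  if (max(group$indices) > nrow(xyz))
    stop_param("atom group '", group$label, "' indexes beyond the coordinates")
  xyz[group$indices, , drop = FALSE]
}

#' Mass-weighted center of mass
#'
#' @param group an [atom_group()].
#' @param xyz n x 3 coordinate matrix (\enc{Å}{A}).
#' @return length-3 position (\enc{Å}{A}).
#' @export
center_of_mass <- function(group, xyz) {
  p <- group_xyz(group, xyz)
  unname(colSums(p * group$masses) / sum(group$masses))
}

#' Oriented major inertia axis of an atom group
#'
#' The long axis of the group: the unit eigenvector of the mass-weighted
#' inertia tensor belonging to its smallest eigenvalue (for an elongated
#' quadruplex, the stacking axis). The eigenvector's sign is fixed by an
#' orientation reference — a bead pair whose separation vector defines
#' the positive direction (by convention 5' end to 3' end, so the 3' side
#' is positive) — making the axis, and every CV built on it,
#' deterministic. A degenerate smallest eigenvalue (relative gap to the
#' next one below 1e-6, e.g. a flat or spherical group) raises an
#' explicit degeneracy error rather than silently picking a direction.
#'
#' @param group an [atom_group()].
#' @param xyz n x 3 coordinates.
#' @param orientation_ref integer pair `c(i, j)`: the axis sign is chosen
#'   so that its dot product with `xyz[j, ] - xyz[i, ]` is >= 0.
#' @return oriented unit 3-vector.
#' @export
major_inertia_axis <- function(group, xyz, orientation_ref) {
  p <- group_xyz(group, xyz)
  if (nrow(p) < 2L) stop_param("inertia axis needs at least 2 beads")
  com <- center_of_mass(group, xyz)
  q <- sweep(p, 2, com)
  if (max(abs(q)) < 1e-12) stop_param("all beads collocated; axis undefined")
  m <- group$masses
  r2 <- rowSums(q^2)
  I <- diag(sum(m * r2), 3) - crossprod(q * sqrt(m))
  # crossprod(q * sqrt(m)) == sum_k m_k q_k q_k^T
  eig <- eigen(I, symmetric = TRUE)
  vals <- rev(eig$values)            # ascending
  vecs <- eig$vectors[, 3:1, drop = FALSE]
  scale <- max(abs(vals))
  if ((vals[2] - vals[1]) / scale < 1e-6)
    stop_degenerate("major inertia axis of '", group$label,
                    "' is degenerate (smallest eigenvalue not unique)")
  axis <- vecs[, 1]
  ref <- xyz[orientation_ref[2], ] - xyz[orientation_ref[1], ]
  if (sum(axis * ref) < 0) axis <- -axis
  axis / sqrt(sum(axis^2))
}

#' Center-of-mass distance between two groups
#'
#' The `d` collective variable: the Euclidean distance between the
#' centers of mass of two groups (receptor and ligand scaffold). By
#' construction it is symmetric in its arguments and assigns the same
#' value to symmetry-equivalent ligand positions around a four-fold
#' symmetric receptor.
#'
#' @param g1,g2 [atom_group()]s.
#' @param xyz n x 3 coordinates.
#' @return distance (\enc{Å}{A}).
#' @export
com_distance <- function(g1, g2, xyz) {
  sqrt(sum((center_of_mass(g1, xyz) - center_of_mass(g2, xyz))^2))
}

dihedral_4pt <- function(p1, p2, p3, p4) {
  b1 <- p2 - p1; b2 <- p3 - p2; b3 <- p4 - p3
  n1 <- c(b1[2] * b2[3] - b1[3] * b2[2],
          b1[3] * b2[1] - b1[1] * b2[3],
          b1[1] * b2[2] - b1[2] * b2[1])
  n2 <- c(b2[2] * b3[3] - b2[3] * b3[2],
          b2[3] * b3[1] - b2[1] * b3[3],
          b2[1] * b3[2] - b2[2] * b3[1])
  m1 <- c(n1[2] * b2[3] - n1[3] * b2[2],
          n1[3] * b2[1] - n1[1] * b2[3],
          n1[1] * b2[2] - n1[2] * b2[1]) / sqrt(sum(b2^2))
  ang <- atan2(sum(m1 * n2), sum(n1 * n2))
  if (ang <= -pi) ang <- ang + 2 * pi
  ang
}

#' Torsion between the inertia axes of two groups
#'
#' The phi/psi collective variable: the dihedral angle between the
#' oriented major inertia axes of two groups, realized as the four-point
#' dihedral of (com1 + axis1, com1, com2, com2 + axis2) — the COM-to-COM
#' vector acts as the central bond. Periodic, in (-pi, pi].
#'
#' @param g1,g2 [atom_group()]s (e.g. ligand and receptor).
#' @param xyz n x 3 coordinates.
#' @param ref1,ref2 orientation reference bead pairs for the two axes.
#' @return torsion angle (rad) in (-pi, pi].
#' @export
axis_torsion <- function(g1, g2, xyz, ref1, ref2) {
  a1 <- major_inertia_axis(g1, xyz, ref1)
  a2 <- major_inertia_axis(g2, xyz, ref2)
  c1 <- center_of_mass(g1, xyz)
  c2 <- center_of_mass(g2, xyz)
  if (sqrt(sum((c1 - c2)^2)) < 1e-8)
    stop_param("centers of mass coincide; torsion undefined")
  dihedral_4pt(c1 + a1, c1, c2, c2 + a2)
}

#' Projection of a group's center of mass on the receptor axis (POA)
#'
#' Signed projection of (COM_point - COM_axis-owner) on the oriented
#' major inertia axis of the axis-owner group. With the default
#' orientation convention (5' to 3'), positive values lie on the 3' side
#' of the receptor. The origin is the axis-owner's center of mass.
#'
#' @param point_group group whose COM is projected (e.g. scaffold).
#' @param axis_group group owning the axis (e.g. quadruplex).
#' @param xyz n x 3 coordinates.
#' @param orientation_ref bead pair fixing the axis sign.
#' @return signed projection (\enc{Å}{A}).
#' @export
projection_on_axis <- function(point_group, axis_group, xyz,
                               orientation_ref) {
  axis <- major_inertia_axis(axis_group, xyz, orientation_ref)
  delta <- center_of_mass(point_group, xyz) -
    center_of_mass(axis_group, xyz)
  sum(delta * axis)
}

#' Distance of a group's center of mass from the receptor axis (DFA)
#'
#' Norm of the component of (COM_point - COM_axis-owner) perpendicular to
#' the oriented axis; together with [projection_on_axis()] it satisfies
#' POA^2 + DFA^2 = |COM_point - COM_axis-owner|^2.
#'
#' @inheritParams projection_on_axis
#' @return perpendicular distance (\enc{Å}{A}, >= 0).
#' @export
distance_from_axis <- function(point_group, axis_group, xyz,
                               orientation_ref) {
  axis <- major_inertia_axis(axis_group, xyz, orientation_ref)
  delta <- center_of_mass(point_group, xyz) -
    center_of_mass(axis_group, xyz)
  perp <- delta - sum(delta * axis) * axis
  sqrt(sum(perp^2))
}

#' Declarative collective-variable specification
#'
#' @param kind one of `"com_distance"`, `"axis_torsion"`,
#'   `"projection_on_axis"`, `"distance_from_axis"`.
#' @param groups list of one or two [atom_group()]s. For
#'   `com_distance`/`axis_torsion`, the two groups; for POA/DFA the first
#'   is the point group, the second the axis-owner group.
#' @param orientation_ref bead pair for the axis sign (required whenever
#'   an inertia axis is used). For `axis_torsion`, a list of two pairs.
#' @param label CV name used in output files.
#' @return Object of class `cv_spec` with `periodic` and `units` filled
#'   in by kind (torsions are periodic, in rad; distances in \enc{Å}{A}).
#' @export
cv_spec <- function(kind, groups, orientation_ref = NULL, label = kind) {
  kind <- match.arg(kind, c("com_distance", "axis_torsion",
                            "projection_on_axis", "distance_from_axis"))
  if (length(groups) != 2L) stop_param(kind, " needs two atom groups")
  needs_axis <- kind != "com_distance"
  if (needs_axis && is.null(orientation_ref))
    stop_param(kind, " needs an orientation reference for the inertia axis")
  structure(list(kind = kind, groups = groups,
                 orientation_ref = orientation_ref, label = label,
                 periodic = kind == "axis_torsion",
                 units = if (kind == "axis_torsion") "rad" else "A"),
            class = "cv_spec")
}

#' Evaluate a collective variable on a configuration
#'
#' @param spec a [cv_spec()].
#' @param xyz n x 3 coordinates.
#' @return scalar CV value (units per the spec).
#' @export
evaluate_cv <- function(spec, xyz) {
  switch(spec$kind,
    com_distance = com_distance(spec$groups[[1]], spec$groups[[2]], xyz),
    axis_torsion = axis_torsion(spec$groups[[1]], spec$groups[[2]], xyz,
                                spec$orientation_ref[[1]],
                                spec$orientation_ref[[2]]),
    projection_on_axis = projection_on_axis(spec$groups[[1]],
                                            spec$groups[[2]], xyz,
                                            spec$orientation_ref),
    distance_from_axis = distance_from_axis(spec$groups[[1]],
                                            spec$groups[[2]], xyz,
                                            spec$orientation_ref))
}

#' Finite-difference gradient of a collective variable
#'
#' Central finite differences with a uniform step, applied identically to
#' every CV kind (including those built on inertia-axis
#' eigendecompositions, for which analytic derivatives would be
#' laborious). Accuracy is O(step^2); periodic CVs are differenced with
#' minimum-image wrapping so the stencil never crosses the branch cut.
#'
#' @param spec a [cv_spec()].
#' @param xyz n x 3 coordinates.
#' @param step finite-difference step (\enc{Å}{A}; default 1e-5).
#' @return n x 3 matrix of partial derivatives of the CV with respect to
#'   every bead coordinate.
#' @export
cv_gradient <- function(spec, xyz, step = 1e-5) {
  idx <- sort(unique(unlist(lapply(spec$groups, `[[`, "indices"))))
  grad <- matrix(0, nrow(xyz), 3)
  wrap <- spec$periodic
  for (i in idx) {
    for (k in 1:3) {
      xp <- xyz; xp[i, k] <- xp[i, k] + step
      xm <- xyz; xm[i, k] <- xm[i, k] - step
      vp <- evaluate_cv(spec, xp)
      vm <- evaluate_cv(spec, xm)
      dv <- vp - vm
      if (wrap) dv <- dv - 2 * pi * round(dv / (2 * pi))
      grad[i, k] <- dv / (2 * step)
    }
  }
  grad
}

#' Upper-wall restraint on a collective variable
#'
#' @param cv label of the restrained CV.
#' @param limit upper limit (default 27.0 \enc{Å}{A}, the wall applied to
#'   the center-of-mass distance to cap the unbound region).
#' @param k spring constant (kcal/mol/\enc{Å}{A}^2).
#' @return Object of class `wall_spec`.
#' @export
wall_spec <- function(cv, limit = 27.0, k = 10) {
  if (limit <= 0) stop_param("wall limit must be positive")
  if (k <= 0) stop_param("wall spring constant must be positive")
  structure(list(cv = cv, limit = limit, k = k), class = "wall_spec")
}

#' Half-harmonic wall energy and derivative
#'
#' Zero below the limit; `k * (value - limit)^2` above, with a continuous
#' derivative at the limit.
#'
#' @param value CV value.
#' @param wall a [wall_spec()].
#' @return list with `energy` (kcal/mol) and `derivative` (kcal/mol per
#'   CV unit).
#' @export
wall_energy <- function(value, wall) {
  over <- pmax(value - wall$limit, 0)
  list(energy = wall$k * over^2, derivative = 2 * wall$k * over)
}
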