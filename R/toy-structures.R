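#' Four-fold-symmetric toy quadruplex bead model
#'
#' Builds a coarse bead model of a parallel tetramolecular quadruplex:
#' four parallel strands of stacked beads sitting on the corners of a
#' square cross-section, stacked along z with a constant rise. The first
#' bead of each strand is the 5' terminus, the last the 3' terminus;
#' terminal beads carry distinct labels and slightly different masses so
#' that, like the real molecule, the model is not symmetric under
#' swapping its ends — the oriented receptor axis can then tell the 3'
#' face from the 5' face. The structure is exactly invariant under a 90
#' degree rotation about its symmetry axis (z) and is centered so its
#' center of mass is at the origin.
#'
#' @param beads_per_strand beads per strand (>= 2).
#' @param rise stacking rise between consecutive beads (\enc{Å}{A}).
#' @param side side of the square cross-section (\enc{Å}{A}).
#' @param mass_core,mass_end5,mass_end3 bead masses (amu).
#' @return Object of class `toy_quadruplex` with fields `xyz` (n x 3),
#'   `mass`, `strand` (`"A"`..`"D"`), `label` (`"end5"`, `"core"`,
#'   `"end3"`) and `axis` (the symmetry axis, `c(0, 0, 1)`).
#' @export
build_toy_quadruplex <- function(beads_per_strand, rise = 3.4, side = 8,
                                 mass_core = 100, mass_end5 = 90,
                                 mass_end3 = 110) {
  if (beads_per_strand < 2) stop_param("beads_per_strand must be >= 2")
  if (rise <= 0 || side <= 0) stop_param("rise and side must be positive")
  half <- side / 2
  corners <- rbind(c(half, half), c(-half, half), c(-half, -half),
                   c(half, -half))
  n <- beads_per_strand
  z <- (seq_len(n) - (n + 1) / 2) * rise      # 5' at the bottom, 3' on top
  xyz <- do.call(rbind, lapply(1:4, function(s)
    cbind(corners[s, 1], corners[s, 2], z)))
  dimnames(xyz) <- NULL
  strand <- rep(c("A", "B", "C", "D"), each = n)
  label <- rep(c("end5", rep("core", n - 2L), "end3"), times = 4)
  mass <- rep(c(mass_end5, rep(mass_core, n - 2L), mass_end3), times = 4)
  com <- colSums(xyz * mass) / sum(mass)
  xyz <- sweep(xyz, 2, com)
  structure(list(xyz = xyz, mass = mass, strand = strand, label = label,
                 axis = c(0, 0, 1), rise = rise, side = side,
                 beads_per_strand = as.integer(beads_per_strand)),
            class = "toy_quadruplex")
}

#' @export
print.toy_quadruplex <- function(x, ...) {
  cat(sprintf(
    "Toy quadruplex: 4 strands x %d beads (rise %g A, side %g A), %d beads\n",
    x$beads_per_strand, x$rise, x$side, nrow(x$xyz)))
  invisible(x)
}

#' Rotate coordinates about the quadruplex symmetry axis
#'
#' @param xyz n x 3 coordinates.
#' @param angle rotation angle (rad); the symmetry operation uses pi/2.
#' @return rotated n x 3 coordinates.
#' @export
rotate_about_z <- function(xyz, angle) {
  R <- matrix(c(cos(angle), sin(angle), 0,
                -sin(angle), cos(angle), 0,
                0, 0, 1), 3, 3)
  xyz %*% R
}

#' Two-bead rigid ligand
#'
#' A rigid two-bead model of the ligand: a heavy "scaffold" bead (the
#' aromatic, quadruplex-contacting moiety) and a lighter "tail" bead (the
#' flexible charged chain), joined by a bond of fixed length. The pose
#' has five degrees of freedom: the scaffold position and the two polar
#' angles of the scaffold-to-tail axis; the bond length never changes
#' under pose moves.
#'
#' @param position scaffold bead position (length-3, \enc{Å}{A}).
#' @param orientation `c(theta, phi)` polar/azimuthal angles (rad) of the
#'   scaffold-to-tail direction.
#' @param bond_length fixed scaffold-tail distance (\enc{Å}{A}).
#' @param masses `c(scaffold, tail)` masses (amu).
#' @return Object of class `rigid_ligand` with fields `xyz` (2 x 3),
#'   `mass`, `label` (`"scaffold"`, `"tail"`), plus the pose parameters.
#' @export
rigid_ligand <- function(position = c(0, 0, 0), orientation = c(pi / 2, 0),
                         bond_length = 4, masses = c(60, 30)) {
  if (bond_length <= 0) stop_param("bond_length must be positive")
  if (any(masses <= 0)) stop_param("masses must be positive")
  dir <- c(sin(orientation[1]) * cos(orientation[2]),
           sin(orientation[1]) * sin(orientation[2]),
           cos(orientation[1]))
  xyz <- rbind(position, position + bond_length * dir)
  rownames(xyz) <- NULL
  structure(list(xyz = xyz, mass = masses, label = c("scaffold", "tail"),
                 position = as.numeric(position),
                 orientation = as.numeric(orientation),
                 bond_length = bond_length),
            class = "rigid_ligand")
}

#' Update a rigid ligand's pose
#'
#' @param ligand a [rigid_ligand()].
#' @param position new scaffold position (default: keep).
#' @param orientation new `c(theta, phi)` (default: keep).
#' @return the ligand with updated coordinates; bond length unchanged.
#' @export
set_pose <- function(ligand, position = NULL, orientation = NULL) {
  rigid_ligand(position %||% ligand$position,
               orientation %||% ligand$orientation,
               bond_length = ligand$bond_length, masses = ligand$mass)
}

#' Assemble a receptor/ligand bead system
#'
#' Concatenates quadruplex and ligand beads into one coordinate set and
#' builds the standard atom groups used by the collective variables:
#' `quadruplex` (all receptor beads), `scaffold`, `tail`, `ligand`, and
#' the axis orientation reference (5'-end bead of strand A to the 3'-end
#' bead of strand A, so the 3' side of the receptor axis is positive).
#'
#' @param quad a [build_toy_quadruplex()] structure.
#' @param ligand a [rigid_ligand()], or `NULL` for the bare receptor.
#' @return list with `xyz`, `mass`, `groups` (named list of
#'   [atom_group()]s) and `orientation_ref` (bead index pair 5' -> 3').
#' @export
assemble_system <- function(quad, ligand = NULL) {
  xyz <- quad$xyz
  mass <- quad$mass
  labels <- quad$label
  nq <- nrow(xyz)
  groups <- list(quadruplex = atom_group(seq_len(nq), quad$mass, "quadruplex"))
  if (!is.null(ligand)) {
    xyz <- rbind(xyz, ligand$xyz)
    mass <- c(mass, ligand$mass)
    groups$scaffold <- atom_group(nq + 1L, ligand$mass[1], "scaffold")
    groups$tail <- atom_group(nq + 2L, ligand$mass[2], "tail")
    groups$ligand <- atom_group(nq + 1:2, ligand$mass, "ligand")
  }
  i5 <- which(quad$strand == "A" & quad$label == "end5")[1]
  i3 <- which(quad$strand == "A" & quad$label == "end3")[1]
  list(xyz = xyz, mass = mass, groups = groups,
       orientation_ref = c(i5, i3))
}

#' Write / read toy structures as PDB
#'
#' Beads are written as CA atoms, the four strands as chains A-D and the
#' ligand as chain L; bead masses are stored in the B-factor column so a
#' written structure round-trips (coordinates to PDB precision, 1e-3
#' \enc{Å}{A}). I/O is delegated to the bio3d package.
#'
#' @param quad a [build_toy_quadruplex()] structure.
#' @param path output file.
#' @param ligand optional [rigid_ligand()].
#' @return `write_structure_pdb` returns `path` invisibly;
#'   `read_structure_pdb` returns a list with `xyz`, `chain`, `mass`.
#' @export
write_structure_pdb <- function(quad, path, ligand = NULL) {
  xyz <- quad$xyz
  chain <- quad$strand
  mass <- quad$mass
  resid <- rep("QUA", nrow(xyz))
  if (!is.null(ligand)) {
    xyz <- rbind(xyz, ligand$xyz)
    chain <- c(chain, rep("L", 2))
    mass <- c(mass, ligand$mass)
    resid <- c(resid, rep("LIG", 2))
  }
  n <- nrow(xyz)
  bio3d::write.pdb(file = path, xyz = as.numeric(t(xyz)),
                   resno = seq_len(n), resid = resid, eleno = seq_len(n),
                   elety = rep("CA", n), chain = chain,
                   o = rep(1, n), b = mass)
  invisible(path)
}

#' @rdname write_structure_pdb
#' @export
read_structure_pdb <- function(path) {
  pdb <- bio3d::read.pdb(path)
  xyz <- matrix(pdb$xyz, ncol = 3, byrow = TRUE)
  list(xyz = xyz, chain = pdb$atom$chain, mass = pdb$atom$b)
}
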