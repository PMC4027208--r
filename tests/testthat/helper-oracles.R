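# Shared fixtures and independent oracles used across the test files.

# simple harmonic well as an analytic potential (k in kcal/mol/A^2)
make_harmonic <- function(k = 2, center = 0, halfwidth = 6) {
  analytic_potential(
    energy = function(X) 0.5 * k * (X[, 1] - center)^2,
    gradient = function(X) cbind(k * (X[, 1] - center)),
    bounds = matrix(c(center - halfwidth, center + halfwidth), 1),
    labels = "x")
}

# brute-force four-point dihedral via the textbook two-plane formula,
# independent of the package's atan2 construction
dihedral_brute <- function(p1, p2, p3, p4) {
  b1 <- p2 - p1; b2 <- p3 - p2; b3 <- p4 - p3
  n1 <- pracma::cross(b1, b2)
  n2 <- pracma::cross(b2, b3)
  cosphi <- sum(n1 * n2) / sqrt(sum(n1^2) * sum(n2^2))
  phi <- acos(pmin(pmax(cosphi, -1), 1))
  # sign matching the documented convention: positive when n1 x n2 is
  # antiparallel to the central bond
  if (sum(pracma::cross(n1, n2) * b2) > 0) phi <- -phi
  phi
}

# random rigid motion (rotation matrix from QR + translation)
random_rigid_motion <- function(seed) {
  set.seed(seed)
  qr_d <- qr(matrix(rnorm(9), 3, 3))
  R <- qr.Q(qr_d)
  if (det(R) < 0) R[, 1] <- -R[, 1]
  list(R = R, t = rnorm(3, sd = 5))
}

apply_rigid <- function(xyz, mot) {
  sweep(xyz %*% t(mot$R), 2, -mot$t)
}

# central finite-difference gradient of an analytic potential
fd_gradient <- function(pot, X, h) {
  g <- matrix(0, nrow(X), pot$dim)
  for (i in seq_len(pot$dim)) {
    Xp <- X; Xp[, i] <- Xp[, i] + h[i]
    Xm <- X; Xm[, i] <- Xm[, i] - h[i]
    g[, i] <- (potential_energy(pot, Xp) - potential_energy(pot, Xm)) /
      (2 * h[i])
  }
  g
}

# exact free-energy surface of an analytic landscape on a regular grid
# (the landscape itself is the ground-truth FES)
exact_fes <- function(pot, bins = 200, temperature = 300) {
  breaks <- lapply(seq_len(pot$dim), function(i)
    seq(pot$bounds[i, 1], pot$bounds[i, 2], length.out = bins + 1L))
  ctr <- lapply(breaks, function(b) (b[-1] + b[-length(b)]) / 2)
  X <- if (pot$dim == 1L) cbind(ctr[[1]]) else
    cbind(rep(ctr[[1]], times = bins), rep(ctr[[2]], each = bins))
  v <- potential_energy(pot, X)
  vals <- if (pot$dim == 1L) v else matrix(v, bins, bins)
  fes_grid(breaks, vals, labels = pot$labels, units = pot$units,
           temperature = temperature)
}

# standard system fixture: quadruplex + ligand placed off-axis
quad_system <- function(beads = 6, lig_pos = c(6, 0, 2)) {
  quad <- build_toy_quadruplex(beads, 3.4, 8)
  lig <- rigid_ligand(position = lig_pos, orientation = c(pi / 3, pi / 5))
  assemble_system(quad, lig)
}
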