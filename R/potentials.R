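#' Analytic energy landscape over one or two collective coordinates
#'
#' An `analytic_potential` plays the role of a known free-energy surface:
#' a smooth energy function with an exact gradient, finite over a stated
#' rectangular domain. It is the synthetic stand-in for the ligand/receptor
#' landscape that downstream sampling, biasing and analysis stages are
#' validated against (via [boltzmann_quadrature()]).
#'
#' @param energy function taking an n x d matrix of points (one row per
#'   point, columns in the order of `labels`) and returning n energies in
#'   kcal/mol.
#' @param gradient function taking the same matrix and returning an n x d
#'   matrix of partial derivatives (kcal/mol per coordinate unit).
#' @param bounds d x 2 matrix of domain bounds (lower, upper) per coordinate.
#' @param labels character vector of coordinate names.
#' @param units per-coordinate units, `"A"` or `"rad"`.
#' @param periodic logical per coordinate; periodic coordinates wrap,
#'   non-periodic ones reflect at the bounds during sampling.
#' @return An object of class `analytic_potential`.
#' @seealso [make_double_well()], [make_hopping_landscape()]
#' @export
analytic_potential <- function(energy, gradient, bounds, labels,
                               units = rep("A", length(labels)),
                               periodic = rep(FALSE, length(labels)),
                               gradient1 = NULL) {
  d <- length(labels)
  bounds <- matrix(as.numeric(bounds), ncol = 2L)
  stopifnot(is.function(energy), is.function(gradient),
            nrow(bounds) == d, all(bounds[, 2] > bounds[, 1]),
            length(units) == d, length(periodic) == d)
  # scalar fast path used in the sampling inner loop
  gradient1 <- gradient1 %||% function(x) gradient(matrix(x, 1L, d))[1L, ]
  structure(list(dim = d, labels = labels, units = units,
                 periodic = as.logical(periodic), bounds = bounds,
                 energy = energy, gradient = gradient,
                 gradient1 = gradient1),
            class = "analytic_potential")
}

#' @export
print.analytic_potential <- function(x, ...) {
  cat("Analytic potential over", x$dim, "coordinate(s):",
      paste0(x$labels, " [", x$units, "]", collapse = ", "), "\n")
  for (i in seq_len(x$dim))
    cat(sprintf("  %s in [%g, %g]%s\n", x$labels[i], x$bounds[i, 1],
                x$bounds[i, 2], if (x$periodic[i]) " (periodic)" else ""))
  invisible(x)
}

#' Evaluate an analytic potential
#'
#' @param potential an [analytic_potential()].
#' @param x a point (numeric vector of length d) or an n x d matrix.
#' @return `potential_energy` returns a numeric vector of energies;
#'   `potential_gradient` an n x d matrix of derivatives.
#' @export
potential_energy <- function(potential, x) {
  potential$energy(as_point_matrix(x, potential$dim))
}

#' @rdname potential_energy
#' @export
potential_gradient <- function(potential, x) {
  potential$gradient(as_point_matrix(x, potential$dim))
}

#' One-dimensional double-well test landscape
#'
#' A quartic double well with minima exactly `separation` apart and, by
#' construction, an energy gap between the two minima equal to `asymmetry`:
#' the asymmetric term is a C1 sigmoid that is exactly 0 at the left
#' minimum and 1 at the right with vanishing slope at both, so the minima
#' stay pinned at \eqn{\pm}separation/2 with energies 0 and `asymmetry`.
#' For `asymmetry = 0` the barrier between the wells equals `barrier`.
#'
#' @param barrier barrier height of the symmetric quartic part (kcal/mol).
#' @param separation distance between the two minima (\enc{Å}{A}).
#' @param asymmetry energy of the right minimum minus the left (kcal/mol).
#' @param label coordinate name (default `"x"`).
#' @return An [analytic_potential()] on the domain
#'   `[-separation, separation]`.
#' @examples
#' dw <- make_double_well(6, 4, 0.9)
#' potential_energy(dw, c(-2, 2))   # 0 and 0.9
#' @export
make_double_well <- function(barrier, separation, asymmetry = 0,
                             label = "x") {
  if (!is.finite(barrier) || barrier <= 0)
    stop_param("barrier must be positive")
  if (!is.finite(separation) || separation <= 0)
    stop_param("separation must be positive")
  a <- separation / 2
  sfun <- function(x) {
    s <- 0.5 * (1 + sin(pi * x / (2 * a)))
    s[x <= -a] <- 0
    s[x >= a] <- 1
    s
  }
  sgrad <- function(x) {
    g <- 0.25 * (pi / a) * cos(pi * x / (2 * a))
    g[x <= -a | x >= a] <- 0
    g
  }
  energy <- function(X) {
    x <- X[, 1]
    barrier * ((x / a)^2 - 1)^2 + asymmetry * sfun(x)
  }
  gradient <- function(X) {
    x <- X[, 1]
    cbind(4 * barrier * x * ((x / a)^2 - 1) / a^2 + asymmetry * sgrad(x))
  }
  gradient1 <- function(x) {
    g <- 4 * barrier * x * ((x / a)^2 - 1) / a^2
    if (x > -a && x < a)
      g <- g + asymmetry * 0.25 * (pi / a) * cos(pi * x / (2 * a))
    g
  }
  analytic_potential(energy, gradient,
                     bounds = matrix(c(-separation, separation), 1),
                     labels = label, gradient1 = gradient1)
}

#' Specification of the three-basin hopping landscape
#'
#' Describes a two-dimensional landscape with three basins labelled
#' `Aa`, `Ab` and `B` — the topology of a ligand hopping between a groove
#' site and an end-stacking site on a quadruplex. Defaults mirror the
#' study conditions: `Ab` and `B` lie 0.9 and 1.4 kcal/mol above the
#' global minimum `Aa`, and the saddle separating `Ab` from `Aa` sits
#' 1.5 kcal/mol above `Ab`. A second channel `Ab`\eqn{\leftrightarrow}`B`
#' (barrier `barrier_ab_b` above the higher minimum) keeps the three
#' basins mutually reachable below the background plateau.
#'
#' @param centers named list of 2D basin centers (\enc{Å}{A}).
#' @param offsets named numeric: free-energy offsets of `Ab` and `B`
#'   relative to `Aa` (kcal/mol), both >= 0.
#' @param barrier Ab<->Aa saddle height above the higher minimum of the
#'   pair (kcal/mol).
#' @param barrier_ab_b Ab<->B saddle height above the higher minimum.
#' @param widths named numeric basin widths (\enc{Å}{A}).
#' @param plateau background plateau height above `Aa` (kcal/mol).
#' @return A list of class `hopping_spec`.
#' @export
hopping_spec <- function(centers = list(Aa = c(0, 0), Ab = c(4, 1.5),
                                        B = c(8, 0)),
                         offsets = c(Ab = 0.9, B = 1.4),
                         barrier = 1.5, barrier_ab_b = 2.0,
                         widths = c(Aa = 1, Ab = 1, B = 1),
                         plateau = 6) {
  nm <- c("Aa", "Ab", "B")
  if (!identical(sort(names(centers)), sort(nm)))
    stop_param("centers must be named Aa, Ab, B")
  centers <- centers[nm]
  offsets <- offsets[c("Ab", "B")]
  widths <- widths[nm]
  if (any(!is.finite(unlist(centers))) || any(lengths(centers) != 2L))
    stop_param("basin centers must be finite 2D points")
  if (any(offsets < 0)) stop_param("basin offsets must be >= 0")
  if (any(widths <= 0)) stop_param("basin widths must be positive")
  if (barrier < max(0, offsets[["Ab"]]))
    stop_param("Ab<->Aa barrier must be at least the offset it separates")
  if (barrier_ab_b <= 0) stop_param("Ab<->B barrier must be positive")
  if (plateau <= max(offsets) + 0.5)
    stop_param("plateau must sit clearly above the highest basin")
  for (pair in list(c(1, 2), c(1, 3), c(2, 3))) {
    dist <- sqrt(sum((centers[[pair[1]]] - centers[[pair[2]]])^2))
    if (dist < 2 * max(widths[pair]))
      stop_param("basin centers ", nm[pair[1]], " and ", nm[pair[2]],
                 " overlap (separation < 2x width)")
  }
  structure(list(centers = centers, offsets = offsets, barrier = barrier,
                 barrier_ab_b = barrier_ab_b, widths = widths,
                 plateau = plateau),
            class = "hopping_spec")
}

# Gaussian channel carved along the segment p -> q: unit depth at the
# saddle (midpoint), decaying with perpendicular distance (width wperp)
# and along the segment (width wt in fractional coordinates).
bridge_value <- function(X, p, q, wperp = 0.9, wt = 0.16) {
  u <- q - p
  L2 <- sum(u^2)
  rp <- sweep(X, 2, p)
  t <- pmin(pmax((rp %*% u) / L2, 0), 1)[, 1]
  foot <- outer(t, u)
  perp2 <- rowSums((rp - foot)^2)
  exp(-perp2 / (2 * wperp^2)) * exp(-(t - 0.5)^2 / (2 * wt^2))
}

bridge_grad1 <- function(x, p, q, wperp = 0.9, wt = 0.16) {
  u1 <- q[1] - p[1]; u2 <- q[2] - p[2]
  L2 <- u1 * u1 + u2 * u2
  r1 <- x[1] - p[1]; r2 <- x[2] - p[2]
  traw <- (r1 * u1 + r2 * u2) / L2
  t <- if (traw < 0) 0 else if (traw > 1) 1 else traw
  f1 <- r1 - t * u1; f2 <- r2 - t * u2
  val <- exp(-(f1 * f1 + f2 * f2) / (2 * wperp^2)) *
    exp(-(t - 0.5)^2 / (2 * wt^2))
  g1 <- -f1 / wperp^2 * val
  g2 <- -f2 / wperp^2 * val
  if (traw > 0 && traw < 1) {
    gt <- -((t - 0.5) / wt^2) * val
    g1 <- g1 + u1 / L2 * gt
    g2 <- g2 + u2 / L2 * gt
  }
  c(g1, g2)
}

bridge_gradient <- function(X, p, q, wperp = 0.9, wt = 0.16) {
  u <- q - p
  L2 <- sum(u^2)
  rp <- sweep(X, 2, p)
  traw <- (rp %*% u)[, 1] / L2
  t <- pmin(pmax(traw, 0), 1)
  inside <- traw > 0 & traw < 1
  foot <- outer(t, u)
  v <- rp - foot                       # perpendicular component (when inside)
  perp2 <- rowSums(v^2)
  val <- exp(-perp2 / (2 * wperp^2)) * exp(-(t - 0.5)^2 / (2 * wt^2))
  # d(perp2)/dr: inside the segment the foot moves with r, and v.u = 0,
  # so d(perp2)/dr = 2 v; outside, t is pinned and d(perp2)/dr = 2 (r - foot)
  dperp2 <- 2 * v
  # d t/dr = u/L2 inside, 0 outside
  g1 <- -dperp2 / (2 * wperp^2) * val
  g2 <- -((t - 0.5) / wt^2) * val
  dt <- matrix(0, nrow(X), 2)
  if (any(inside))
    dt[inside, ] <- matrix(u / L2, sum(inside), 2, byrow = TRUE)
  g1 + dt * g2
}

#' Three-basin hopping landscape with calibrated depths and barrier
#'
#' Builds the two-dimensional landscape described by a [hopping_spec()]:
#' a flat plateau with three Gaussian basins whose minimum energies are
#' calibrated to the requested offsets, connected by two lowered channels
#' whose saddle heights are calibrated to the requested barriers. The
#' calibration is a deterministic fixed-point iteration (local
#' minimisation of each basin, line search over each channel) run at
#' construction time; minima land within 0.1 \enc{Å}{A} of the specified
#' centers and within 0.05 kcal/mol of the specified offsets.
#'
#' @param spec a [hopping_spec()] (default: study-condition defaults).
#' @return An [analytic_potential()] in coordinates `cv1`, `cv2`.
#' @export
make_hopping_landscape <- function(spec = hopping_spec()) {
  if (!inherits(spec, "hopping_spec")) stop_param("spec must be a hopping_spec")
  cen <- do.call(rbind, spec$centers)
  w <- as.numeric(spec$widths)
  plateau <- spec$plateau
  target <- c(0, spec$offsets[["Ab"]], spec$offsets[["B"]])
  D <- plateau - target
  bridges <- list(list(i = 2L, j = 1L, barrier = spec$barrier),
                  list(i = 2L, j = 3L, barrier = spec$barrier_ab_b))
  A <- vapply(bridges, function(b) {
    max(0, plateau - (max(target[c(b$i, b$j)]) + b$barrier))
  }, numeric(1))

  make_fun <- function(D, A) {
    energy <- function(X) {
      e <- rep(plateau, nrow(X))
      for (k in 1:3) {
        d2 <- (X[, 1] - cen[k, 1])^2 + (X[, 2] - cen[k, 2])^2
        e <- e - D[k] * exp(-d2 / (2 * w[k]^2))
      }
      for (bi in seq_along(bridges)) {
        b <- bridges[[bi]]
        e <- e - A[bi] * bridge_value(X, cen[b$i, ], cen[b$j, ])
      }
      e
    }
    gradient <- function(X) {
      g <- matrix(0, nrow(X), 2)
      for (k in 1:3) {
        dx <- X[, 1] - cen[k, 1]; dy <- X[, 2] - cen[k, 2]
        ek <- D[k] * exp(-(dx^2 + dy^2) / (2 * w[k]^2)) / w[k]^2
        g[, 1] <- g[, 1] + ek * dx
        g[, 2] <- g[, 2] + ek * dy
      }
      for (bi in seq_along(bridges)) {
        b <- bridges[[bi]]
        g <- g - A[bi] * bridge_gradient(X, cen[b$i, ], cen[b$j, ])
      }
      g
    }
    gradient1 <- function(x) {
      g1 <- 0; g2 <- 0
      for (k in 1:3) {
        dx <- x[1] - cen[k, 1]; dy <- x[2] - cen[k, 2]
        ek <- D[k] * exp(-(dx * dx + dy * dy) / (2 * w[k]^2)) / w[k]^2
        g1 <- g1 + ek * dx; g2 <- g2 + ek * dy
      }
      for (bi in seq_along(bridges)) {
        b <- bridges[[bi]]
        gb <- bridge_grad1(x, cen[b$i, ], cen[b$j, ])
        g1 <- g1 - A[bi] * gb[1]; g2 <- g2 - A[bi] * gb[2]
      }
      c(g1, g2)
    }
    list(energy = energy, gradient = gradient, gradient1 = gradient1)
  }

  mins <- cen
  for (iter in 1:8) {
    f <- make_fun(D, A)
    emin <- numeric(3)
    for (k in 1:3) {
      opt <- stats::optim(mins[k, ], fn = function(p) f$energy(rbind(p)),
                          gr = function(p) f$gradient(rbind(p))[1, ],
                          method = "BFGS",
                          control = list(reltol = 1e-12, maxit = 200))
      mins[k, ] <- opt$par
      emin[k] <- opt$value
    }
    # re-anchor: depths corrected so basin minima hit their targets
    shift <- emin[1]
    D <- D + (emin - shift - target)
    # channel amplitudes corrected so line-maximum saddles hit their targets
    f <- make_fun(D, A)
    for (bi in seq_along(bridges)) {
      b <- bridges[[bi]]
      tt <- seq(0, 1, length.out = 601)
      line <- cbind(mins[b$i, 1] + tt * (mins[b$j, 1] - mins[b$i, 1]),
                    mins[b$i, 2] + tt * (mins[b$j, 2] - mins[b$i, 2]))
      saddle <- max(f$energy(line))
      want <- max(target[c(b$i, b$j)]) + b$barrier
      A[bi] <- A[bi] + (saddle - shift - want)
    }
    if (any(A < 0)) stop_param("channel calibration failed: barrier too high for plateau")
  }
  f <- make_fun(D, A)
  e0 <- min(vapply(1:3, function(k) {
    stats::optim(mins[k, ], fn = function(p) f$energy(rbind(p)),
                 gr = function(p) f$gradient(rbind(p))[1, ],
                 method = "BFGS", control = list(reltol = 1e-12))$value
  }, numeric(1)))
  margin <- 3.5
  bounds <- rbind(range(cen[, 1]) + c(-margin, margin),
                  range(cen[, 2]) + c(-margin, margin))
  pot <- analytic_potential(function(X) f$energy(X) - e0, f$gradient,
                            bounds = bounds, labels = c("cv1", "cv2"),
                            gradient1 = f$gradient1)
  pot$spec <- spec
  pot$basin_centers <- mins
  pot
}

#' Boltzmann quadrature over a region of an analytic potential
#'
#' Trapezoidal quadrature of \eqn{\exp(-E/kT)} over a rectangular region,
#' returning the configurational partition mass and the region free energy
#' \eqn{-kT \log(\mathrm{mass})}. This is the package's independent oracle
#' for everything the sampling and biasing stages estimate statistically.
#'
#' @param potential an [analytic_potential()].
#' @param kT thermal energy (kcal/mol).
#' @param region list of `c(lower, upper)` per coordinate; default the
#'   full domain.
#' @param n quadrature points per axis (default 801).
#' @return list with `mass`, `free_energy` (kcal/mol) and `n`.
#' @export
boltzmann_quadrature <- function(potential, kT, region = NULL, n = 801) {
  d <- potential$dim
  if (is.null(region))
    region <- lapply(seq_len(d), function(i) potential$bounds[i, ])
  if (length(region) != d) stop_param("region must have one range per coordinate")
  axes <- vector("list", d)
  wts <- vector("list", d)
  for (i in seq_len(d)) {
    r <- as.numeric(region[[i]])
    if (length(r) != 2 || !all(is.finite(r)) || r[2] <= r[1])
      stop_param("empty or invalid region on coordinate ", potential$labels[i])
    if (r[1] < potential$bounds[i, 1] - 1e-9 ||
        r[2] > potential$bounds[i, 2] + 1e-9)
      stop_param("region outside the potential domain on ", potential$labels[i])
    axes[[i]] <- seq(r[1], r[2], length.out = n)
    h <- (r[2] - r[1]) / (n - 1)
    wi <- rep(h, n); wi[c(1, n)] <- h / 2
    wts[[i]] <- wi
  }
  if (d == 1L) {
    E <- potential$energy(cbind(axes[[1]]))
    mass <- sum(wts[[1]] * exp(-E / kT))
  } else {
    X <- cbind(rep(axes[[1]], times = n), rep(axes[[2]], each = n))
    E <- potential$energy(X)
    W <- rep(wts[[1]], times = n) * rep(wts[[2]], each = n)
    mass <- sum(W * exp(-E / kT))
  }
  list(mass = mass, free_energy = -kT * log(mass), n = n)
}

#' Quadrature marginal free-energy profile along one coordinate
#'
#' Integrates the Boltzmann weight over the other coordinate(s) to give
#' the exact marginal free-energy profile on a set of bins — the oracle
#' against which reweighted surfaces are compared.
#'
#' @param potential a 1D or 2D [analytic_potential()].
#' @param kT thermal energy (kcal/mol).
#' @param axis index of the coordinate to keep (1 or 2).
#' @param breaks bin edges along that coordinate.
#' @param n_inner quadrature points over the integrated coordinate and
#'   within each bin.
#' @return A [fes_grid()] (1D), minimum-anchored at zero.
#' @export
quadrature_marginal_fes <- function(potential, kT, axis, breaks,
                                    n_inner = 201) {
  d <- potential$dim
  if (!axis %in% seq_len(d)) stop_param("axis out of range")
  breaks <- sort(as.numeric(breaks))
  nb <- length(breaks) - 1L
  mass <- numeric(nb)
  other <- setdiff(seq_len(d), axis)
  for (b in seq_len(nb)) {
    xs <- seq(breaks[b], breaks[b + 1], length.out = 33)
    hx <- diff(breaks[b:(b + 1)]) / 32
    wx <- rep(hx, 33); wx[c(1, 33)] <- hx / 2
    if (d == 1L) {
      E <- potential$energy(cbind(xs))
      mass[b] <- sum(wx * exp(-E / kT))
    } else {
      ys <- seq(potential$bounds[other, 1], potential$bounds[other, 2],
                length.out = n_inner)
      hy <- (potential$bounds[other, 2] - potential$bounds[other, 1]) /
        (n_inner - 1)
      wy <- rep(hy, n_inner); wy[c(1, n_inner)] <- hy / 2
      X <- matrix(0, 33 * n_inner, 2)
      X[, axis] <- rep(xs, times = n_inner)
      X[, other] <- rep(ys, each = 33)
      E <- potential$energy(X)
      W <- rep(wx, times = n_inner) * rep(wy, each = 33)
      mass[b] <- sum(W * exp(-E / kT))
    }
  }
  p <- mass / sum(mass) / diff(breaks)
  f <- -kT * log(p)
  fes_grid(breaks = list(breaks), values = f - min(f),
           labels = potential$labels[axis], units = potential$units[axis],
           temperature = kT / kB)
}
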