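#' Well-tempered metadynamics parameters
#'
#' The study-condition defaults: simulation temperature 300 K, a CV
#' "overtemperature" \eqn{\Delta T} of 2700 K (bias factor
#' \eqn{\gamma = (T+\Delta T)/T = 10}), and an initial Gaussian
#' deposition rate of 0.5 kcal/mol/ps split, by convention, into an
#' initial height `w0` of 0.5 kcal/mol deposited every `tau` = 1 ps.
#' Default Gaussian widths are 0.23 \enc{Å}{A} for distance-like CVs and
#' 0.05 rad for torsions.
#'
#' @param temperature simulation temperature T (K).
#' @param delta_t \eqn{\Delta T} (K): the difference between the CV
#'   temperature and the simulation temperature.
#' @param w0 initial Gaussian height (kcal/mol).
#' @param tau deposition pace (ps); the initial rate is `w0/tau`.
#' @param widths Gaussian width per biased CV (\enc{Å}{A} or rad).
#'   `NULL`: chosen by CV unit (0.23 \enc{Å}{A} / 0.05 rad).
#' @param grid_min,grid_max,grid_bins bias grid specification per biased
#'   CV. `NULL`: derived from the sampled domain, extended 3 widths
#'   beyond it.
#' @return Object of class `wt_params`.
#' @export
wt_params <- function(temperature = 300, delta_t = 2700, w0 = 0.5,
                      tau = 1, widths = NULL, grid_min = NULL,
                      grid_max = NULL, grid_bins = NULL) {
  if (temperature <= 0 || delta_t <= 0) stop_param("T and delta_t must be positive")
  if (w0 <= 0 || tau <= 0) stop_param("w0 and tau must be positive")
  if (!is.null(widths) && any(widths <= 0)) stop_param("widths must be positive")
  structure(list(temperature = temperature, delta_t = delta_t, w0 = w0,
                 tau = tau, widths = widths, grid_min = grid_min,
                 grid_max = grid_max, grid_bins = grid_bins,
                 rate = w0 / tau),
            class = "wt_params")
}

#' Tempered Gaussian height
#'
#' The well-tempered deposition rule: a hill dropped where the bias has
#' already accumulated to `v_here` gets height
#' \eqn{w_0 \exp(-V/(k_B \Delta T))}, so the deposition rate decays as
#' the bias grows and the bias converges instead of overfilling.
#'
#' @param w0 initial height (kcal/mol).
#' @param v_here current bias at the deposition point (kcal/mol, >= 0).
#' @param delta_t \eqn{\Delta T} (K).
#' @return tempered height (kcal/mol).
#' @export
tempered_height <- function(w0, v_here, delta_t) {
  if (any(v_here < -1e-12)) stop_param("bias value must be non-negative")
  w0 * exp(-v_here / (kB * delta_t))
}

default_width_for_unit <- function(units) {
  ifelse(units == "rad", 0.05, 0.23)
}

#' History-dependent metadynamics bias
#'
#' A `bias_state` holds the deposited hills together with an
#' incrementally maintained grid cache of the bias energy \eqn{V(s)} and
#' its per-CV forces, used as the fast path during dynamics. It is an
#' environment: [deposit()] updates it in place. The grid cache agrees
#' with direct hill summation to better than 1e-6 kcal/mol (hill
#' contributions are truncated 8 widths out).
#'
#' @param params a [wt_params()].
#' @param labels biased CV labels.
#' @param units,periodic per-CV units and periodicity.
#' @param default_bounds d x 2 matrix used for the grid when `params`
#'   does not specify one; the grid then extends 3 widths beyond it.
#' @return Object of classes `bias_state` and `environment`.
#' @export
new_bias_state <- function(params, labels, units = NULL, periodic = NULL,
                           default_bounds = NULL) {
  d <- length(labels)
  units <- units %||% rep("A", d)
  periodic <- periodic %||% rep(FALSE, d)
  widths <- rep_len(params$widths %||% default_width_for_unit(units), d)
  gmin <- params$grid_min
  gmax <- params$grid_max
  if (is.null(gmin) || is.null(gmax)) {
    if (is.null(default_bounds))
      stop_param("no grid bounds given and no domain to derive them from")
    gmin <- gmin %||% (default_bounds[, 1] - ifelse(periodic, 0, 3 * widths))
    gmax <- gmax %||% (default_bounds[, 2] + ifelse(periodic, 0, 3 * widths))
  }
  gmin <- rep_len(as.numeric(gmin), d)
  gmax <- rep_len(as.numeric(gmax), d)
  nb <- rep_len(as.integer(params$grid_bins %||%
                             pmax(101L, ceiling((gmax - gmin) / (widths / 10)))),
                d)
  if (any(gmax <= gmin)) stop_param("grid bounds inverted")
  e <- new.env(parent = emptyenv())
  e$dim <- d; e$labels <- labels; e$units <- units; e$periodic <- periodic
  e$widths <- widths
  e$temperature <- params$temperature; e$delta_t <- params$delta_t
  e$w0 <- params$w0; e$tau <- params$tau
  e$gmin <- gmin; e$gmax <- gmax; e$nbins <- nb
  e$gstep <- (gmax - gmin) / (nb - 1L)
  e$centers <- lapply(seq_len(d), function(i) seq(gmin[i], gmax[i],
                                                  length.out = nb[i]))
  zero <- if (d == 1L) numeric(nb[1]) else matrix(0, nb[1], nb[2])
  e$V <- zero
  e$Fg <- lapply(seq_len(d), function(i) zero)
  e$hills <- matrix(0, 256L, 2L * d + 2L)
  colnames(e$hills) <- c("time", paste0("center_", labels),
                         paste0("sigma_", labels), "height")
  e$n_hills <- 0L
  class(e) <- c("bias_state", "environment")
  e
}

#' @export
print.bias_state <- function(x, ...) {
  cat(sprintf("Metadynamics bias on %s: %d hills, grid %s\n",
              paste(x$labels, collapse = ", "), x$n_hills,
              paste(x$nbins, collapse = " x ")))
  if (x$n_hills > 0)
    cat(sprintf("  V max %.4f kcal/mol; last deposit at %.4g ps\n",
                max(x$V), x$hills[x$n_hills, 1]))
  invisible(x)
}

#' Deposited hills as a matrix
#' @param bias a [new_bias_state()].
#' @return matrix with one row per hill: time, centers, widths, height.
#' @export
hills_matrix <- function(bias) {
  bias$hills[seq_len(bias$n_hills), , drop = FALSE]
}

min_image <- function(dz, periodic, span) {
  if (any(periodic)) {
    for (i in which(periodic))
      dz[, i] <- dz[, i] - span[i] * round(dz[, i] / span[i])
  }
  dz
}

# add one Gaussian to the cached V and force grids; exact at the nodes
# within an 8-sigma window (full axis for periodic CVs)
add_hill_to_grid <- function(e, center, height, sigma = e$widths) {
  d <- e$dim
  idx <- vector("list", d)
  gauss <- vector("list", d)
  dz_ax <- vector("list", d)
  for (i in seq_len(d)) {
    if (e$periodic[i]) {
      ii <- seq_len(e$nbins[i])
    } else {
      lo <- max(1L, 1L + floor((center[i] - 8 * sigma[i] - e$gmin[i]) /
                                 e$gstep[i]))
      hi <- min(e$nbins[i], 1L + ceiling((center[i] + 8 * sigma[i] -
                                            e$gmin[i]) / e$gstep[i]))
      if (hi < lo) return(invisible(e))
      ii <- lo:hi
    }
    dz <- e$centers[[i]][ii] - center[i]
    if (e$periodic[i]) {
      span <- e$gmax[i] - e$gmin[i]
      dz <- dz - span * round(dz / span)
    }
    idx[[i]] <- ii
    dz_ax[[i]] <- dz
    gauss[[i]] <- exp(-dz^2 / (2 * sigma[i]^2))
  }
  if (d == 1L) {
    g <- height * gauss[[1]]
    e$V[idx[[1]]] <- e$V[idx[[1]]] + g
    e$Fg[[1]][idx[[1]]] <- e$Fg[[1]][idx[[1]]] +
      g * dz_ax[[1]] / sigma[1]^2
  } else {
    g <- height * outer(gauss[[1]], gauss[[2]])
    e$V[idx[[1]], idx[[2]]] <- e$V[idx[[1]], idx[[2]]] + g
    e$Fg[[1]][idx[[1]], idx[[2]]] <- e$Fg[[1]][idx[[1]], idx[[2]]] +
      g * (dz_ax[[1]] / sigma[1]^2)
    e$Fg[[2]][idx[[1]], idx[[2]]] <- e$Fg[[2]][idx[[1]], idx[[2]]] +
      g * rep(dz_ax[[2]] / sigma[2]^2, each = length(idx[[1]]))
  }
  invisible(e)
}

#' Deposit one tempered hill
#'
#' Appends a Gaussian centered at the current CV position, with height
#' tempered by the bias already accumulated there (evaluated by direct
#' summation over previous hills), and updates the grid cache
#' incrementally. The bias state is modified in place.
#'
#' @param bias a [new_bias_state()].
#' @param center CV position of the hill.
#' @param t deposition time (ps); must exceed the previous deposition
#'   time by at least `tau`.
#' @param params the [wt_params()] of the run.
#' @return the updated bias state, invisibly.
#' @export
deposit <- function(bias, center, t, params = NULL) {
  d <- bias$dim
  center <- as.numeric(center)
  if (length(center) != d) stop_param("hill center has wrong dimension")
  if (any(center < bias$gmin - 1e-9 | center > bias$gmax + 1e-9))
    stop_param("hill center outside the bias grid; the grid must cover ",
               "the walled domain")
  w0 <- if (is.null(params)) bias$w0 else params$w0
  tau <- if (is.null(params)) bias$tau else params$tau
  if (bias$n_hills > 0L) {
    tlast <- bias$hills[bias$n_hills, 1]
    if (t - tlast < tau - 1e-9)
      stop_param("deposition pace violated: t must exceed the last ",
                 "deposition time by at least tau")
  }
  v_here <- if (bias$n_hills == 0L) 0 else bias_energy(bias, center)
  h <- tempered_height(w0, v_here, bias$delta_t)
  if (bias$n_hills == nrow(bias$hills)) {
    grown <- matrix(0, 2L * nrow(bias$hills), ncol(bias$hills))
    colnames(grown) <- colnames(bias$hills)
    grown[seq_len(bias$n_hills), ] <- bias$hills[seq_len(bias$n_hills), ]
    bias$hills <- grown
  }
  bias$n_hills <- bias$n_hills + 1L
  bias$hills[bias$n_hills, ] <- c(t, center, bias$widths, h)
  add_hill_to_grid(bias, center, h)
  invisible(bias)
}

#' Bias energy at a point
#'
#' Direct summation over hills (the reference path), with minimum-image
#' differences on periodic CVs; or a Catmull-Rom cubic read-out of the
#' grid cache (the fast path), which at the default grid spacing of one
#' tenth of a hill width agrees with direct summation to better than
#' 1e-4 kcal/mol.
#'
#' @param bias a [new_bias_state()].
#' @param s a CV point (length d) or an n x d matrix of points.
#' @param method `"direct"` or `"grid"`.
#' @param max_hills sum only the first so many hills (used to evaluate
#'   the bias "as of" an earlier time); default all.
#' @return numeric vector of bias energies (kcal/mol).
#' @export
bias_energy <- function(bias, s, method = c("direct", "grid"),
                        max_hills = NULL) {
  method <- match.arg(method)
  S <- as_point_matrix(s, bias$dim)
  if (method == "grid")
    return(vapply(seq_len(nrow(S)),
                  function(i) bias_grid_energy_cubic(bias, S[i, ]),
                  numeric(1)))
  n <- max_hills %||% bias$n_hills
  if (n == 0L) return(numeric(nrow(S)))
  H <- bias$hills[seq_len(n), , drop = FALSE]
  d <- bias$dim
  span <- bias$gmax - bias$gmin
  out <- numeric(nrow(S))
  for (p in seq_len(nrow(S))) {
    expo <- 0
    for (i in seq_len(d)) {
      dz <- S[p, i] - H[, 1L + i]
      if (bias$periodic[i]) dz <- dz - span[i] * round(dz / span[i])
      expo <- expo + dz^2 / (2 * H[, 1L + d + i]^2)
    }
    out[p] <- sum(H[, 2L * d + 2L] * exp(-expo))
  }
  out
}

#' Bias force at a point
#'
#' Analytic Gaussian derivatives summed over hills:
#' \eqn{-\partial V/\partial s} per CV.
#'
#' @inheritParams bias_energy
#' @param s a CV point (length d).
#' @return numeric vector of forces (kcal/mol per CV unit).
#' @export
bias_force <- function(bias, s, max_hills = NULL) {
  d <- bias$dim
  s <- as.numeric(s)
  n <- max_hills %||% bias$n_hills
  if (n == 0L) return(numeric(d))
  H <- bias$hills[seq_len(n), , drop = FALSE]
  span <- bias$gmax - bias$gmin
  dzs <- matrix(0, n, d)
  expo <- 0
  for (i in seq_len(d)) {
    dz <- s[i] - H[, 1L + i]
    if (bias$periodic[i]) dz <- dz - span[i] * round(dz / span[i])
    dzs[, i] <- dz
    expo <- expo + dz^2 / (2 * H[, 1L + d + i]^2)
  }
  g <- H[, 2L * d + 2L] * exp(-expo)
  vapply(seq_len(d),
         function(i) sum(g * dzs[, i] / H[, 1L + d + i]^2), numeric(1))
}

# Catmull-Rom weights for fractional offset u in [0, 1] on a 4-node
# stencil; the accurate off-node read-out of the grid cache
cr_weights <- function(u) {
  c((-u^3 + 2 * u^2 - u) / 2,
    (3 * u^3 - 5 * u^2 + 2) / 2,
    (-3 * u^3 + 4 * u^2 + u) / 2,
    (u^3 - u^2) / 2)
}

cr_stencil <- function(e, i, s) {
  u <- (s - e$gmin[i]) / e$gstep[i]
  j <- min(max(floor(u), 1), e$nbins[i] - 3L)  # clamp so j-1 .. j+2 exist
  list(idx = j:(j + 3L), w = cr_weights(u - j)) # 1-based: nodes j .. j+3
}

bias_grid_energy_cubic <- function(e, s) {
  if (e$dim == 1L) {
    st <- cr_stencil(e, 1L, s[1])
    sum(e$V[st$idx] * st$w)
  } else {
    s1 <- cr_stencil(e, 1L, s[1])
    s2 <- cr_stencil(e, 2L, s[2])
    as.numeric(s1$w %*% e$V[s1$idx, s2$idx] %*% s2$w)
  }
}

# fast linear interpolation used in the dynamics inner loop
bias_grid_energy <- function(e, s) {
  if (e$dim == 1L) {
    u <- (s[1] - e$gmin[1]) / e$gstep[1]
    j <- min(max(floor(u), 0), e$nbins[1] - 2L)
    w <- u - j
    e$V[j + 1L] * (1 - w) + e$V[j + 2L] * w
  } else {
    u1 <- (s[1] - e$gmin[1]) / e$gstep[1]
    j1 <- min(max(floor(u1), 0), e$nbins[1] - 2L); w1 <- u1 - j1
    u2 <- (s[2] - e$gmin[2]) / e$gstep[2]
    j2 <- min(max(floor(u2), 0), e$nbins[2] - 2L); w2 <- u2 - j2
    (e$V[j1 + 1L, j2 + 1L] * (1 - w1) + e$V[j1 + 2L, j2 + 1L] * w1) *
      (1 - w2) +
      (e$V[j1 + 1L, j2 + 2L] * (1 - w1) + e$V[j1 + 2L, j2 + 2L] * w1) * w2
  }
}

bias_grid_force <- function(e, s) {
  if (e$dim == 1L) {
    u <- (s[1] - e$gmin[1]) / e$gstep[1]
    j <- min(max(floor(u), 0), e$nbins[1] - 2L)
    w <- u - j
    e$Fg[[1]][j + 1L] * (1 - w) + e$Fg[[1]][j + 2L] * w
  } else {
    u1 <- (s[1] - e$gmin[1]) / e$gstep[1]
    j1 <- min(max(floor(u1), 0), e$nbins[1] - 2L); w1 <- u1 - j1
    u2 <- (s[2] - e$gmin[2]) / e$gstep[2]
    j2 <- min(max(floor(u2), 0), e$nbins[2] - 2L); w2 <- u2 - j2
    c((e$Fg[[1]][j1 + 1L, j2 + 1L] * (1 - w1) +
         e$Fg[[1]][j1 + 2L, j2 + 1L] * w1) * (1 - w2) +
        (e$Fg[[1]][j1 + 1L, j2 + 2L] * (1 - w1) +
           e$Fg[[1]][j1 + 2L, j2 + 2L] * w1) * w2,
      (e$Fg[[2]][j1 + 1L, j2 + 1L] * (1 - w1) +
         e$Fg[[2]][j1 + 2L, j2 + 1L] * w1) * (1 - w2) +
        (e$Fg[[2]][j1 + 1L, j2 + 2L] * (1 - w1) +
           e$Fg[[2]][j1 + 2L, j2 + 2L] * w1) * w2)
  }
}

#' Check the grid cache against direct hill summation
#'
#' @param bias a [new_bias_state()].
#' @param n number of random grid nodes to probe.
#' @param seed RNG seed for the probe points.
#' @return maximum absolute discrepancy (kcal/mol) between the cached
#'   node values and direct summation.
#' @export
check_grid_cache <- function(bias, n = 100, seed = 1) {
  set.seed(seed)
  d <- bias$dim
  worst <- 0
  for (k in seq_len(n)) {
    ij <- vapply(seq_len(d), function(i) sample.int(bias$nbins[i], 1L),
                 integer(1))
    s <- vapply(seq_len(d), function(i) bias$centers[[i]][ij[i]], numeric(1))
    cached <- if (d == 1L) bias$V[ij[1]] else bias$V[ij[1], ij[2]]
    worst <- max(worst, abs(cached - bias_energy(bias, s)))
  }
  worst
}

#' Verify the tempered-height law on a bias history
#'
#' Recomputes, for every hill, the bias accumulated at its center by the
#' hills deposited before it, applies the well-tempered rule and
#' compares with the stored height. Useful to validate HILLS files.
#'
#' @param bias a [new_bias_state()] (e.g. read back with [read_hills()]).
#' @return maximum absolute height discrepancy (kcal/mol).
#' @export
check_tempered_heights <- function(bias) {
  n <- bias$n_hills
  if (n == 0L) return(0)
  d <- bias$dim
  worst <- 0
  for (k in seq_len(n)) {
    ctr <- bias$hills[k, 1L + seq_len(d)]
    v <- if (k == 1L) 0 else bias_energy(bias, ctr, max_hills = k - 1L)
    worst <- max(worst, abs(bias$hills[k, 2L * d + 2L] -
                              tempered_height(bias$w0, v, bias$delta_t)))
  }
  worst
}

#' Free-energy surface from the accumulated bias
#'
#' The well-tempered estimate
#' \eqn{F(s) = -\frac{T+\Delta T}{\Delta T} V(s)} evaluated on the bias
#' grid and anchored so its minimum is zero. With the study temperatures
#' (300 K / 2700 K) the scaling factor is 10/9.
#'
#' @param bias a [new_bias_state()].
#' @param temperature,delta_t temperatures (K); default those stored in
#'   the bias.
#' @param anchor shift the minimum to zero (default TRUE).
#' @return A [fes_grid()] over the bias grid (all bins visited).
#' @export
fes_from_bias <- function(bias, temperature = bias$temperature,
                          delta_t = bias$delta_t, anchor = TRUE) {
  fac <- (temperature + delta_t) / delta_t
  f <- -fac * bias$V
  breaks <- lapply(seq_len(bias$dim), function(i)
    seq(bias$gmin[i] - bias$gstep[i] / 2, bias$gmax[i] + bias$gstep[i] / 2,
        length.out = bias$nbins[i] + 1L))
  fes_grid(breaks, f, labels = bias$labels, units = bias$units,
           temperature = temperature, anchor = anchor)
}

#' Run well-tempered metadynamics on an analytic landscape
#'
#' Alternates overdamped Langevin segments of length `tau` with tempered
#' hill deposits at the current position of the biased CVs. Any subset
#' of the landscape coordinates may be biased (`bias_cvs`); unbiased
#' coordinates evolve under the bare potential, which is how surfaces
#' are later reweighted onto them. Deterministic for a given seed.
#'
#' @param potential an [analytic_potential()].
#' @param wt a [wt_params()].
#' @param ld a [langevin_params()] (its `nsteps` and `seed` drive the
#'   run).
#' @param walls optional list of [wall_spec()]s on coordinates.
#' @param bias_cvs indices of the coordinates to bias (default: all).
#' @param x0 initial coordinate (default: domain midpoint).
#' @param stride record every `stride`-th step.
#' @return list with `trajectory` (a [cv_trajectory()]) and `bias` (the
#'   final [new_bias_state()]).
#' @export
run_metadynamics <- function(potential, wt, ld, walls = NULL,
                             bias_cvs = NULL, x0 = NULL, stride = 10L) {
  ld_engine(potential, ld, walls = walls, stride = stride, x0 = x0,
            bias_cvs = bias_cvs, wt = wt)
}
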