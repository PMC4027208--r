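#' Overdamped Langevin sampler parameters
#'
#' Parameters of the Brownian (overdamped Euler--Maruyama) integrator
#' used to sample analytic landscapes. The stationary distribution of
#' the scheme is the Boltzmann distribution at `temperature`; the
#' mobility per coordinate is \eqn{D = k_B T / (m \gamma)} (with the
#' kcal/mol to amu \enc{Å}{A}\eqn{^2}/ps\eqn{^2} conversion applied), so
#' `mass` and `friction` only set the time scale of exploration, never
#' the sampled ensemble.
#'
#' @param temperature temperature (K).
#' @param friction friction coefficient (1/ps).
#' @param timestep integration step (ps).
#' @param mass particle mass (amu), scalar or one per coordinate.
#' @param nsteps number of steps.
#' @param seed RNG seed; every source of randomness in a run flows from
#'   it.
#' @return Object of class `langevin_params`.
#' @export
langevin_params <- function(temperature = 300, friction = 50,
                            timestep = 0.02, mass = 40, nsteps = 1e5,
                            seed = 1) {
  if (temperature <= 0) stop_param("temperature must be positive")
  if (friction <= 0) stop_param("friction must be positive")
  if (timestep <= 0) stop_param("timestep must be positive")
  if (any(mass <= 0)) stop_param("mass must be positive")
  if (nsteps < 1) stop_param("nsteps must be at least 1")
  structure(list(temperature = temperature, friction = friction,
                 timestep = timestep, mass = mass,
                 nsteps = as.integer(nsteps), seed = as.integer(seed)),
            class = "langevin_params")
}

#' Collective-variable trajectory
#'
#' Per-frame record of a sampling run: times (ps), CV values and the
#' instantaneous bias energy (zero for unbiased runs).
#'
#' @param time frame times (ps), strictly increasing.
#' @param values n x d matrix of CV values, columns named by CV label.
#' @param bias instantaneous bias energy per frame (kcal/mol).
#' @param units,periodic per-CV units and periodicity.
#' @return Object of class `cv_trajectory`.
#' @export
cv_trajectory <- function(time, values, bias = NULL, units = NULL,
                          periodic = NULL) {
  values <- as.matrix(values)
  n <- length(time)
  if (nrow(values) != n) stop_param("frame count mismatch between time and values")
  if (n > 1 && any(diff(time) <= 0)) stop_param("times must be strictly increasing")
  bias <- bias %||% rep(0, n)
  if (length(bias) != n) stop_param("bias record length mismatch")
  d <- ncol(values)
  structure(list(time = as.numeric(time), values = values,
                 bias = as.numeric(bias),
                 labels = colnames(values) %||% paste0("cv", seq_len(d)),
                 units = units %||% rep("A", d),
                 periodic = periodic %||% rep(FALSE, d)),
            class = "cv_trajectory")
}

#' Restrict a trajectory to a time window
#'
#' Commonly used to drop the initial transient of a metadynamics run
#' (while the bias is still growing fast) before reweighting.
#'
#' @param traj a [cv_trajectory()].
#' @param from,to time window (ps), inclusive.
#' @return the windowed [cv_trajectory()].
#' @export
subset_trajectory <- function(traj, from = 0, to = Inf) {
  keep <- traj$time >= from & traj$time <= to
  if (!any(keep)) stop_param("no frames in the requested window")
  out <- cv_trajectory(traj$time[keep], traj$values[keep, , drop = FALSE],
                       traj$bias[keep], units = traj$units,
                       periodic = traj$periodic)
  out$reflections <- traj$reflections
  out
}

#' @export
print.cv_trajectory <- function(x, ...) {
  cat(sprintf("CV trajectory: %d frames, %.4g ps, CVs: %s\n",
              length(x$time), if (length(x$time)) max(x$time) else 0,
              paste(x$labels, collapse = ", ")))
  invisible(x)
}

# Shared overdamped-dynamics engine. When `wt` is supplied the run is a
# well-tempered metadynamics run: segments of tau are alternated with
# hill deposits at the current biased-CV position. `bias` may also be a
# fixed (non-growing) bias acting on the dynamics.
ld_engine <- function(potential, ld, bias = NULL, walls = NULL,
                      stride = 10L, x0 = NULL, bias_cvs = NULL,
                      wt = NULL) {
  d <- potential$dim
  lo <- potential$bounds[, 1]
  hi <- potential$bounds[, 2]
  periodic <- potential$periodic
  span <- hi - lo
  x <- if (is.null(x0)) (lo + hi) / 2 else as.numeric(x0)
  if (length(x) != d) stop_param("x0 must have one value per coordinate")
  if (any(x < lo - 1e-9 | x > hi + 1e-9))
    stop_param("initial coordinate outside the potential domain")
  kT <- kB * ld$temperature
  mass <- rep_len(ld$mass, d)
  D <- kT * KCAL_TO_AKMA / (mass * ld$friction)   # A^2/ps
  dt <- ld$timestep
  mobdt <- D / kT * dt
  sig <- sqrt(2 * D * dt)
  d_loc <- d
  gradfun <- potential$gradient1 %||%
    function(z) potential$gradient(matrix(z, 1L, d_loc))[1L, ]
  nsteps <- ld$nsteps
  stride <- as.integer(stride)

  wall_idx <- integer(0); wall_lim <- numeric(0); wall_k <- numeric(0)
  for (w in walls %||% list()) {
    wi <- match(w$cv, potential$labels)
    if (is.na(wi)) stop_param("wall CV '", w$cv, "' is not a coordinate")
    wall_idx <- c(wall_idx, wi); wall_lim <- c(wall_lim, w$limit)
    wall_k <- c(wall_k, w$k)
  }

  depositing <- !is.null(wt)
  if (depositing) {
    bias_cvs <- bias_cvs %||% seq_len(d)
    steps_per_seg <- max(1L, as.integer(round(wt$tau / dt)))
    if (is.null(bias))
      bias <- new_bias_state(wt, labels = potential$labels[bias_cvs],
                             units = potential$units[bias_cvs],
                             periodic = potential$periodic[bias_cvs],
                             default_bounds = potential$bounds[bias_cvs, ,
                                                               drop = FALSE])
  } else if (!is.null(bias)) {
    bias_cvs <- bias_cvs %||% match(bias$labels, potential$labels)
    if (anyNA(bias_cvs)) stop_param("bias CV labels do not match coordinates")
  }
  has_bias <- !is.null(bias)

  set.seed(ld$seed)
  nframes <- nsteps %/% stride
  rec_t <- numeric(nframes); rec_x <- matrix(0, nframes, d)
  rec_v <- numeric(nframes); iframe <- 0L
  reflections <- 0L
  step <- 0L
  while (step < nsteps) {
    nseg <- if (depositing) min(steps_per_seg, nsteps - step) else nsteps - step
    noise <- matrix(stats::rnorm(nseg * d), nseg, d)
    for (i in seq_len(nseg)) {
      gU <- gradfun(x)
      if (has_bias) {
        fb <- bias_grid_force(bias, x[bias_cvs])
        gU[bias_cvs] <- gU[bias_cvs] - fb
      }
      if (length(wall_idx)) {
        over <- x[wall_idx] - wall_lim
        pos <- over > 0
        if (any(pos))
          gU[wall_idx[pos]] <- gU[wall_idx[pos]] +
            2 * wall_k[pos] * over[pos]
      }
      x <- x - mobdt * gU + sig * noise[i, ]
      for (j in seq_len(d)) {
        if (periodic[j]) {
          x[j] <- lo[j] + (x[j] - lo[j]) %% span[j]
        } else if (x[j] < lo[j] || x[j] > hi[j]) {
          reflections <- reflections + 1L
          while (x[j] < lo[j] || x[j] > hi[j]) {
            if (x[j] < lo[j]) x[j] <- 2 * lo[j] - x[j]
            if (x[j] > hi[j]) x[j] <- 2 * hi[j] - x[j]
          }
        }
      }
      step <- step + 1L
      if (step %% stride == 0L) {
        iframe <- iframe + 1L
        rec_t[iframe] <- step * dt
        rec_x[iframe, ] <- x
        rec_v[iframe] <- if (has_bias) bias_grid_energy(bias, x[bias_cvs]) else 0
      }
    }
    if (depositing && step < nsteps + 1L)
      deposit(bias, x[bias_cvs], t = step * dt, params = wt)
  }
  colnames(rec_x) <- potential$labels
  traj <- cv_trajectory(rec_t[seq_len(iframe)],
                        rec_x[seq_len(iframe), , drop = FALSE],
                        rec_v[seq_len(iframe)],
                        units = potential$units, periodic = periodic)
  traj$reflections <- reflections
  list(trajectory = traj, bias = bias)
}

#' Sample an analytic potential with overdamped Langevin dynamics
#'
#' Brownian dynamics on the potential's coordinates (for analytic
#' landscapes the coordinates are themselves the collective variables).
#' An optional fixed bias and half-harmonic walls enter the total force
#' as \eqn{-\nabla(U + V + W)}. Non-periodic coordinates reflect at the
#' domain bounds (excursions are counted in the returned trajectory's
#' `reflections` field); periodic coordinates wrap. Identical seed and
#' inputs give a bit-identical trajectory.
#'
#' @param potential an [analytic_potential()].
#' @param params a [langevin_params()].
#' @param bias optional [bias_state()] acting on (a subset of) the
#'   coordinates; it is not grown during the run.
#' @param walls optional list of [wall_spec()]s.
#' @param x0 initial coordinate (default: domain midpoint).
#' @param stride record every `stride`-th step.
#' @return A [cv_trajectory()].
#' @export
langevin_run <- function(potential, params, bias = NULL, walls = NULL,
                         x0 = NULL, stride = 10L) {
  ld_engine(potential, params, bias = bias, walls = walls, stride = stride,
            x0 = x0)$trajectory
}
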