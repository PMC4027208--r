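#' Time-dependent bias offset c(t)
#'
#' The reweighting of a well-tempered run uses per-frame weights
#' \eqn{\exp(\beta [V(s(t),t) - c(t)])}, where
#' \deqn{c(t) = \frac{1}{\beta}\ln
#'   \frac{\int ds\, e^{-\beta F(s,t)}}{\int ds\, e^{-\beta(F(s,t)+V(s,t))}}}
#' with \eqn{F(s,t) = -\frac{T+\Delta T}{\Delta T} V(s,t)}. The integrals
#' are evaluated by trapezoidal quadrature on the bias grid after
#' replaying the hill history up to each checkpoint. With no hills
#' deposited, c = 0.
#'
#' @param bias a [new_bias_state()] holding the full hill history.
#' @param checkpoints times (ps) at which to evaluate c(t); typically a
#'   subsample of the deposition times, interpolated linearly in
#'   between by [frame_weights()].
#' @param temperature,delta_t temperatures (K); default those stored in
#'   the bias.
#' @return data.frame of class `ct_series` with columns `time`, `c`.
#' @export
compute_ct <- function(bias, checkpoints, temperature = bias$temperature,
                       delta_t = bias$delta_t) {
  checkpoints <- sort(as.numeric(checkpoints))
  beta <- 1 / (kB * temperature)
  fac <- (temperature + delta_t) / delta_t
  d <- bias$dim
  wts <- integration_weights(bias)
  n <- bias$n_hills
  H <- hills_matrix(bias)
  V <- if (d == 1L) numeric(bias$nbins[1]) else
    matrix(0, bias$nbins[1], bias$nbins[2])
  replay <- replay_state(bias)
  cvals <- numeric(length(checkpoints))
  k <- 1L
  for (ci in seq_along(checkpoints)) {
    while (k <= n && H[k, 1] <= checkpoints[ci] + 1e-12) {
      add_hill_to_grid(replay, H[k, 1L + seq_len(d)],
                       H[k, 2L * d + 2L],
                       sigma = H[k, 1L + d + seq_len(d)])
      k <- k + 1L
    }
    V <- replay$V
    if (k == 1L) {
      cvals[ci] <- 0
    } else {
      F <- -fac * V
      num <- sum(wts * exp(-beta * F))
      den <- sum(wts * exp(-beta * (F + V)))
      cvals[ci] <- log(num / den) / beta
    }
  }
  structure(data.frame(time = checkpoints, c = cvals),
            class = c("ct_series", "data.frame"))
}

# trapezoid weights over the bias grid nodes
integration_weights <- function(bias) {
  d <- bias$dim
  w1 <- rep(bias$gstep[1], bias$nbins[1])
  w1[c(1, bias$nbins[1])] <- bias$gstep[1] / 2
  if (d == 1L) return(w1)
  w2 <- rep(bias$gstep[2], bias$nbins[2])
  w2[c(1, bias$nbins[2])] <- bias$gstep[2] / 2
  outer(w1, w2)
}

# empty clone of a bias state's grid, for replaying hill histories
replay_state <- function(bias) {
  e <- new.env(parent = emptyenv())
  for (f in c("dim", "labels", "units", "periodic", "widths", "temperature",
              "delta_t", "w0", "tau", "gmin", "gmax", "nbins", "gstep",
              "centers"))
    assign(f, get(f, envir = bias), envir = e)
  zero <- if (e$dim == 1L) numeric(e$nbins[1]) else
    matrix(0, e$nbins[1], e$nbins[2])
  e$V <- zero
  e$Fg <- lapply(seq_len(e$dim), function(i) zero)
  e$n_hills <- 0L
  class(e) <- c("bias_state", "environment")
  e
}

#' Per-frame unbiasing weights
#'
#' Normalized weights \eqn{w_t \propto \exp(\beta [V(s(t),t) - c(t)])}
#' that reconstruct the unbiased Boltzmann distribution from a biased
#' trajectory. The instantaneous bias is taken from the trajectory
#' record; frames with a missing record are recomputed from the hills
#' deposited before the frame time (the fallback is reported via
#' `message()`). c(t) is interpolated linearly between checkpoints.
#'
#' @param traj a [cv_trajectory()] from a biased run.
#' @param bias the run's [new_bias_state()].
#' @param ct a [compute_ct()] series (`NULL` for an unbiased run: all
#'   weights equal).
#' @param temperature temperature (K).
#' @return Object of class `weight_series`: list with `time` and
#'   `weights` (non-negative, summing to one).
#' @export
frame_weights <- function(traj, bias = NULL, ct = NULL, temperature = 300) {
  nf <- length(traj$time)
  beta <- 1 / (kB * temperature)
  if (is.null(bias) || is.null(ct) ||
      (is.null(bias$n_hills) || bias$n_hills == 0L)) {
    w <- rep(1 / nf, nf)
    return(structure(list(time = traj$time, weights = w),
                     class = "weight_series"))
  }
  v <- traj$bias
  miss <- !is.finite(v)
  if (any(miss)) {
    message("frame_weights: recomputing the bias for ", sum(miss),
            " frame(s) with no recorded value")
    H <- hills_matrix(bias)
    d <- bias$dim
    cols <- match(bias$labels, traj$labels)
    if (anyNA(cols)) stop_param("trajectory lacks the biased CV columns")
    for (i in which(miss)) {
      nh <- sum(H[, 1] <= traj$time[i] + 1e-12)
      v[i] <- if (nh == 0L) 0 else
        bias_energy(bias, traj$values[i, cols], max_hills = nh)
    }
  }
  cvals <- stats::approx(ct$time, ct$c, xout = traj$time, rule = 2)$y
  logw <- beta * (v - cvals)
  logw <- logw - max(logw)
  w <- exp(logw)
  w <- w / sum(w)
  structure(list(time = traj$time, weights = w), class = "weight_series")
}

#' @export
print.weight_series <- function(x, ...) {
  cat(sprintf("Frame weights: %d frames, effective sample size %.1f\n",
              length(x$weights), 1 / sum(x$weights^2)))
  invisible(x)
}

#' Free-energy surface along new collective variables by reweighting
#'
#' Weighted histogram of the trajectory over the requested CVs, turned
#' into a free-energy surface \eqn{F = -kT \log p} on the occupied bins,
#' minimum-anchored at zero. Bins never visited are flagged unvisited
#' (`NA`), not imputed. The new CVs need not be the biased ones: any
#' per-frame column of the trajectory can be used, which is how a run
#' biased along one coordinate yields surfaces along another.
#'
#' @param traj a [cv_trajectory()].
#' @param weights a [frame_weights()] result, or a numeric vector of
#'   per-frame weights.
#' @param cv names (or indices) of 1 or 2 trajectory CV columns.
#' @param breaks list of bin-edge vectors (or a single vector for 1D).
#' @param temperature temperature (K) for the \eqn{-kT \log p} map.
#' @return A [fes_grid()] with occupancy counts.
#' @export
reweighted_fes <- function(traj, weights, cv, breaks, temperature = 300) {
  w <- if (inherits(weights, "weight_series")) weights$weights else
    as.numeric(weights)
  if (length(w) != length(traj$time))
    stop_param("one weight per frame required")
  if (any(w < 0)) stop_param("weights must be non-negative")
  cols <- if (is.numeric(cv)) as.integer(cv) else match(cv, traj$labels)
  if (anyNA(cols)) stop_param("unknown CV column: ", paste(cv, collapse = ", "))
  d <- length(cols)
  if (!d %in% 1:2) stop_param("reweighted FES supports 1 or 2 CVs")
  if (!is.list(breaks)) breaks <- list(breaks)
  if (length(breaks) != d) stop_param("need one break vector per CV")
  nb <- vapply(breaks, function(b) length(b) - 1L, integer(1))
  idx <- matrix(0L, length(w), d)
  keep <- rep(TRUE, length(w))
  for (i in seq_len(d)) {
    v <- traj$values[, cols[i]]
    ii <- findInterval(v, breaks[[i]], rightmost.closed = TRUE)
    keep <- keep & ii >= 1L & ii <= nb[i]
    idx[, i] <- ii
  }
  w <- w[keep]
  idx <- idx[keep, , drop = FALSE]
  if (length(w) == 0L) stop_param("no frames fall inside the requested bins")
  lin <- if (d == 1L) idx[, 1] else idx[, 1] + (idx[, 2] - 1L) * nb[1]
  nbin_tot <- prod(nb)
  wsum <- numeric(nbin_tot)
  acc <- rowsum(w, lin)
  wsum[as.integer(rownames(acc))] <- acc[, 1]
  counts <- tabulate(lin, nbin_tot)
  if (sum(wsum > 0) == 1L)
    warning("degenerate FES: all weight falls in a single bin")
  area <- if (d == 1L) diff(breaks[[1]]) else
    as.numeric(outer(diff(breaks[[1]]), diff(breaks[[2]])))
  p <- wsum / sum(wsum) / area
  f <- ifelse(wsum > 0, -kB * temperature * log(p), NA_real_)
  if (d == 2L) {
    f <- matrix(f, nb[1], nb[2])
    counts <- matrix(counts, nb[1], nb[2])
  }
  labs <- traj$labels[cols]
  fes_grid(breaks, f, labels = labs, units = traj$units[cols],
           temperature = temperature, counts = counts)
}
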