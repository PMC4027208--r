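#' Local minima and watershed basins of a free-energy surface
#'
#' Detects local minima (bins strictly lower than all visited
#' neighbours; 4-connectivity in 2D) with \eqn{F \le} `depth_cutoff`,
#' and assigns every visited bin to a basin by flooding in order of
#' increasing free energy: each bin joins the basin of its
#' lowest-energy already-assigned neighbour, ties broken by bin order,
#' so the segmentation is deterministic. Basins whose minimum lies
#' above the cutoff are merged into the neighbouring basin with the
#' lowest shared boundary.
#'
#' @param fes a [fes_grid()].
#' @param depth_cutoff keep only minima with F at most this (kcal/mol).
#' @return list of basins sorted by depth, each of class `fes_basin`
#'   with `label`, `location` (bin-center coordinates of the minimum),
#'   `fmin`, `members` (linear bin indices), `prob` (basin-integrated
#'   Boltzmann probability) and `min_bin`.
#' @export
find_minima <- function(fes, depth_cutoff = Inf) {
  d <- fes$dim
  nb <- vapply(fes$breaks, function(b) length(b) - 1L, integer(1))
  ntot <- prod(nb)
  vals <- as.numeric(fes$values)
  visited <- as.logical(fes$visited)
  if (!any(visited)) stop_param("FES has no visited bins")
  neigh <- function(i) {
    if (d == 1L) {
      out <- c(i - 1L, i + 1L)
      out[out >= 1L & out <= ntot]
    } else {
      r <- ((i - 1L) %% nb[1]) + 1L
      cc <- ((i - 1L) %/% nb[1]) + 1L
      out <- integer(0)
      if (r > 1L) out <- c(out, i - 1L)
      if (r < nb[1]) out <- c(out, i + 1L)
      if (cc > 1L) out <- c(out, i - nb[1])
      if (cc < nb[2]) out <- c(out, i + nb[1])
      out
    }
  }
  ord <- which(visited)[order(vals[visited], which(visited))]
  assign <- integer(ntot)
  seed_bins <- integer(0)
  for (i in ord) {
    nbrs <- neigh(i)
    nbrs <- nbrs[visited[nbrs] & assign[nbrs] > 0L]
    if (length(nbrs) == 0L) {
      seed_bins <- c(seed_bins, i)
      assign[i] <- length(seed_bins)
    } else {
      assign[i] <- assign[nbrs[which.min(vals[nbrs])]]
    }
  }
  fmins <- vals[seed_bins]
  # merge basins whose minimum misses the cutoff into their lowest-saddle
  # neighbouring basin
  keep <- fmins <= depth_cutoff
  if (!any(keep)) {
    warning("no minima at or below the depth cutoff")
    return(list())
  }
  for (b in order(fmins, decreasing = TRUE)) {
    if (keep[b]) next
    members <- which(assign == b)
    best_target <- 0L; best_saddle <- Inf
    for (i in members) {
      for (j in neigh(i)) {
        if (visited[j] && assign[j] != b && assign[j] > 0L) {
          sdl <- max(vals[i], vals[j])
          if (sdl < best_saddle) { best_saddle <- sdl; best_target <- assign[j] }
        }
      }
    }
    if (best_target > 0L) assign[members] <- best_target
    else assign[members] <- 0L          # isolated shallow component: dropped
  }
  ids <- which(keep)
  ids <- ids[order(fmins[ids])]
  centers <- fes_centers(fes)
  areas <- if (d == 1L) diff(fes$breaks[[1]]) else
    as.numeric(outer(diff(fes$breaks[[1]]), diff(fes$breaks[[2]])))
  kT <- kB * fes$temperature
  tot <- sum(exp(-vals[visited] / kT) * areas[visited])
  grid_id <- paste(vapply(fes$breaks, function(b)
    paste0(length(b), ":", b[1], ":", b[length(b)]), character(1)),
    collapse = "|")
  out <- lapply(seq_along(ids), function(k) {
    b <- ids[k]
    members <- which(assign == b)
    i <- seed_bins[b]
    loc <- if (d == 1L) centers[[1]][i] else
      c(centers[[1]][((i - 1L) %% nb[1]) + 1L],
        centers[[2]][((i - 1L) %/% nb[1]) + 1L])
    structure(list(label = paste0("M", k), location = loc,
                   fmin = vals[i], min_bin = i, members = members,
                   prob = sum(exp(-vals[members] / kT) * areas[members]) / tot,
                   grid_id = grid_id),
              class = "fes_basin")
  })
  out
}

#' @export
print.fes_basin <- function(x, ...) {
  cat(sprintf("Basin %s: min F = %.3f kcal/mol at (%s), %d bins, P = %.3f\n",
              x$label, x$fmin, paste(sprintf("%.2f", x$location),
                                     collapse = ", "),
              length(x$members), x$prob))
  invisible(x)
}

check_same_grid <- function(a, b) {
  if (!identical(a$grid_id, b$grid_id))
    stop_param("basins come from different grids")
}

#' Free-energy difference between two basins
#'
#' In `"minimum"` mode (the convention used when reading depths off a
#' plotted surface) the difference of the basin minima,
#' \eqn{F_{min}(b) - F_{min}(a)}, positive when `a` is deeper; in
#' `"integral"` mode the thermodynamically consistent
#' \eqn{-kT\log(P_a/P_b)} from basin-integrated probabilities, i.e. the
#' basin free energy of `a` minus that of `b` (negative when `a` is the
#' more populated). Both are invariant under uniform shifts of the
#' surface.
#'
#' @param fes the [fes_grid()] both basins belong to.
#' @param a,b basins from [find_minima()] on `fes`.
#' @param mode `"minimum"` (default) or `"integral"`.
#' @return free-energy difference (kcal/mol).
#' @export
basin_delta_g <- function(fes, a, b, mode = c("minimum", "integral")) {
  mode <- match.arg(mode)
  check_same_grid(a, b)
  if (mode == "minimum") {
    b$fmin - a$fmin
  } else {
    -kB * fes$temperature * log(a$prob / b$prob)
  }
}

#' Lowest-saddle barrier between two basins
#'
#' The minimal, over all paths through visited bins, of the path's
#' maximal free energy — found exactly by activating bins in order of
#' increasing F and union-joining neighbours until the two minima become
#' connected (a threshold flood-fill). The barrier is reported relative
#' to the higher of the two minima.
#'
#' @param fes a [fes_grid()].
#' @param a,b basins from [find_minima()] on `fes`.
#' @return barrier height (kcal/mol); 0 if the minima coincide.
#' @export
barrier_height <- function(fes, a, b) {
  check_same_grid(a, b)
  if (a$min_bin == b$min_bin) return(0)
  d <- fes$dim
  nb <- vapply(fes$breaks, function(b) length(b) - 1L, integer(1))
  ntot <- prod(nb)
  vals <- as.numeric(fes$values)
  visited <- as.logical(fes$visited)
  parent <- seq_len(ntot)
  find <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }
  active <- logical(ntot)
  ord <- which(visited)[order(vals[visited], which(visited))]
  for (i in ord) {
    active[i] <- TRUE
    nbrs <- if (d == 1L) c(i - 1L, i + 1L) else {
      r <- ((i - 1L) %% nb[1]) + 1L
      cc <- ((i - 1L) %/% nb[1]) + 1L
      out <- integer(0)
      if (r > 1L) out <- c(out, i - 1L)
      if (r < nb[1]) out <- c(out, i + 1L)
      if (cc > 1L) out <- c(out, i - nb[1])
      if (cc < nb[2]) out <- c(out, i + nb[1])
      out
    }
    for (j in nbrs) {
      if (j >= 1L && j <= ntot && active[j]) {
        rj <- find(j); ri <- find(i)
        if (ri != rj) parent[rj] <- ri
      }
    }
    if (find(a$min_bin) == find(b$min_bin))
      return(vals[i] - max(a$fmin, b$fmin))
  }
  stop_param("basins are not connected through visited bins")
}

#' Bound and unbound regions on the distance CV
#'
#' Defaults follow the study's state definitions on the center-of-mass
#' distance d: bound for 7.0 <= d <= 14.0 \enc{Å}{A}, unbound for
#' 24 < d < 26 \enc{Å}{A}.
#'
#' @param bound,unbound `c(lower, upper)` ranges (\enc{Å}{A}).
#' @return Object of class `binding_regions`.
#' @export
binding_regions <- function(bound = c(7, 14), unbound = c(24, 26)) {
  bound <- as.numeric(bound); unbound <- as.numeric(unbound)
  if (bound[2] <= bound[1] || unbound[2] <= unbound[1])
    stop_param("regions must be non-empty ranges")
  if (bound[2] >= unbound[1])
    stop_param("bound region must lie entirely below the unbound region")
  structure(list(bound = bound, unbound = unbound),
            class = "binding_regions")
}

region_mass <- function(fes, range, name, temperature) {
  edges <- fes$breaks[[1]]
  ov <- pmax(0, pmin(edges[-1], range[2]) - pmax(edges[-length(edges)],
                                                 range[1]))
  sel <- ov > 0 & fes$visited
  if (!any(sel))
    stop_param("the ", name, " region overlaps no visited bins")
  kT <- kB * temperature
  list(mass = sum(exp(-fes$values[sel] / kT) * ov[sel]),
       fmin = min(fes$values[sel]))
}

#' Binding free energy from a 1D distance FES
#'
#' \deqn{\Delta G = -kT \log
#'   \frac{\sum_{bound} e^{-F/kT}\,\Delta d}{\sum_{unbound} e^{-F/kT}\,\Delta d}}
#' over bins overlapping each region (partial bins enter with their
#' overlap length), or, in `"minimum"` mode, the difference of the
#' region minima. Following the direct FES-difference definition, no
#' standard-state volume correction is applied unless requested, in
#' which case \eqn{-kT\log(V_u/V_0)} is added.
#'
#' @param fes a 1D [fes_grid()] along the distance CV.
#' @param regions a [binding_regions()].
#' @param mode `"integral"` (default) or `"minimum"`.
#' @param temperature temperature (K); default the grid's.
#' @param standard_state apply the volume correction (default FALSE).
#' @param unbound_volume,standard_volume volumes (\enc{Å}{A}^3) for the
#'   optional correction; `standard_volume` defaults to 1661
#'   \enc{Å}{A}^3 (1 M).
#' @return Object of class `binding_free_energy` with `delta_g`
#'   (kcal/mol), `uncertainty` (NA here; see [delta_g_uncertainty()]),
#'   `mode` and `regions`.
#' @export
binding_delta_g <- function(fes, regions = binding_regions(),
                            mode = c("integral", "minimum"),
                            temperature = fes$temperature,
                            standard_state = FALSE, unbound_volume = NULL,
                            standard_volume = 1661) {
  mode <- match.arg(mode)
  if (fes$dim != 1L) stop_param("binding_delta_g needs a 1D FES")
  kT <- kB * temperature
  b <- region_mass(fes, regions$bound, "bound", temperature)
  u <- region_mass(fes, regions$unbound, "unbound", temperature)
  dg <- if (mode == "integral") -kT * log(b$mass / u$mass) else
    b$fmin - u$fmin
  if (standard_state) {
    if (is.null(unbound_volume))
      stop_param("unbound_volume required for the standard-state correction")
    dg <- dg - kT * log(unbound_volume / standard_volume)
  }
  structure(list(delta_g = dg, uncertainty = NA_real_, mode = mode,
                 regions = regions, temperature = temperature),
            class = "binding_free_energy")
}

#' @export
print.binding_free_energy <- function(x, ...) {
  cat(sprintf("Binding free energy (%s mode): %.3f kcal/mol", x$mode,
              x$delta_g))
  if (is.finite(x$uncertainty)) cat(sprintf(" +/- %.3f", x$uncertainty))
  cat(sprintf("  [bound %.1f-%.1f A, unbound %.1f-%.1f A]\n",
              x$regions$bound[1], x$regions$bound[2],
              x$regions$unbound[1], x$regions$unbound[2]))
  invisible(x)
}

#' Convergence of the binding free energy over simulation time
#'
#' Replays the hill history, evaluates the well-tempered FES estimate at
#' each checkpoint and computes the bound/unbound free-energy difference
#' from it — the profile whose flattening signals a converged estimate.
#' If the trajectory is supplied, the number of bound/unbound
#' recrossings (each crossing between consecutive visits to the two
#' regions counts one) is reported alongside: repeated recrossings are
#' the precondition for trusting the final value.
#'
#' @param bias a 1D [new_bias_state()] on the distance CV.
#' @param checkpoints times (ps) at which to evaluate \eqn{\Delta G(t)}.
#' @param regions a [binding_regions()].
#' @param temperature,delta_t temperatures (K); default from the bias.
#' @param trajectory optional [cv_trajectory()] for the recrossing
#'   count.
#' @param mode passed to [binding_delta_g()].
#' @return Object of class `convergence_profile`: list with `profile`
#'   (data.frame `time`, `delta_g`) and `recrossings` (NA without a
#'   trajectory).
#' @export
convergence_profile <- function(bias, checkpoints,
                                regions = binding_regions(),
                                temperature = bias$temperature,
                                delta_t = bias$delta_t,
                                trajectory = NULL,
                                mode = "integral") {
  if (bias$dim != 1L)
    stop_param("convergence profile needs a 1D bias on the distance CV")
  checkpoints <- sort(as.numeric(checkpoints))
  if (length(checkpoints) < 2L) stop_param("need at least 2 checkpoints")
  fac <- (temperature + delta_t) / delta_t
  H <- hills_matrix(bias)
  replay <- replay_state(bias)
  breaks <- seq(bias$gmin[1] - bias$gstep[1] / 2,
                bias$gmax[1] + bias$gstep[1] / 2,
                length.out = bias$nbins[1] + 1L)
  k <- 1L
  dg <- numeric(length(checkpoints))
  for (ci in seq_along(checkpoints)) {
    while (k <= nrow(H) && H[k, 1] <= checkpoints[ci] + 1e-12) {
      add_hill_to_grid(replay, H[k, 2], H[k, 4], sigma = H[k, 3])
      k <- k + 1L
    }
    fes <- fes_grid(list(breaks), -fac * replay$V, labels = bias$labels,
                    units = bias$units, temperature = temperature)
    dg[ci] <- binding_delta_g(fes, regions, mode = mode,
                              temperature = temperature)$delta_g
  }
  rec <- NA_integer_
  if (!is.null(trajectory)) {
    col <- match(bias$labels[1], trajectory$labels)
    if (is.na(col)) col <- 1L
    rec <- count_recrossings(trajectory$values[, col], regions)
  }
  structure(list(profile = data.frame(time = checkpoints, delta_g = dg),
                 recrossings = rec),
            class = "convergence_profile")
}

#' @export
print.convergence_profile <- function(x, ...) {
  n <- nrow(x$profile)
  cat(sprintf("Binding dG convergence: %d checkpoints, final %.3f kcal/mol",
              n, x$profile$delta_g[n]))
  if (!is.na(x$recrossings)) cat(sprintf(", %d recrossings", x$recrossings))
  cat("\n")
  invisible(x)
}

#' Count bound/unbound recrossings along a distance series
#'
#' @param values distance CV values per frame (\enc{Å}{A}).
#' @param regions a [binding_regions()].
#' @return number of transitions between consecutive visits to the
#'   bound and unbound regions.
#' @export
count_recrossings <- function(values, regions = binding_regions()) {
  state <- integer(length(values))
  state[values >= regions$bound[1] & values <= regions$bound[2]] <- 1L
  state[values > regions$unbound[1] & values < regions$unbound[2]] <- 2L
  s <- state[state > 0L]
  if (length(s) == 0L) return(0L)
  r <- rle(s)$values
  length(r) - 1L
}

#' Block standard error of the binding free energy
#'
#' Splits the trajectory into contiguous blocks, reweights each block
#' independently into a 1D distance FES and computes the bound/unbound
#' free-energy difference per block; the reported uncertainty is the
#' sample standard error over block values. Blocks in which a region is
#' never visited are skipped (reported via `message()`).
#'
#' @param traj a [cv_trajectory()].
#' @param weights a [frame_weights()] result.
#' @param regions a [binding_regions()].
#' @param n_blocks number of contiguous blocks (>= 2).
#' @param cv trajectory column holding the distance CV.
#' @param breaks bin edges for the per-block FES (default: 100 bins over
#'   the column range).
#' @param temperature temperature (K).
#' @return standard error (kcal/mol).
#' @export
delta_g_uncertainty <- function(traj, weights, regions = binding_regions(),
                                n_blocks = 4, cv = 1, breaks = NULL,
                                temperature = 300) {
  if (n_blocks < 2) stop_param("need at least 2 blocks")
  w <- if (inherits(weights, "weight_series")) weights$weights else
    as.numeric(weights)
  nf <- length(traj$time)
  col <- if (is.numeric(cv)) as.integer(cv) else match(cv, traj$labels)
  v <- traj$values[, col]
  breaks <- breaks %||% seq(min(v), max(v), length.out = 101)
  grp <- cut(seq_len(nf), n_blocks, labels = FALSE)
  vals <- c()
  for (b in seq_len(n_blocks)) {
    sel <- grp == b
    sub <- cv_trajectory(traj$time[sel], traj$values[sel, , drop = FALSE],
                         traj$bias[sel], units = traj$units,
                         periodic = traj$periodic)
    dg <- tryCatch({
      fes <- reweighted_fes(sub, w[sel] / sum(w[sel]), cv = col,
                            breaks = breaks, temperature = temperature)
      binding_delta_g(fes, regions, temperature = temperature)$delta_g
    }, error = function(e) {
      message("delta_g_uncertainty: block ", b, " skipped (",
              conditionMessage(e), ")")
      NA_real_
    })
    vals <- c(vals, dg)
  }
  vals <- vals[is.finite(vals)]
  if (length(vals) < 2L) stop_param("fewer than 2 usable blocks")
  stats::sd(vals) / sqrt(length(vals))
}
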