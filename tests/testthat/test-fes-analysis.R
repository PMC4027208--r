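test_that("watershed minima recover the hopping landscape basins", {
  hl <- make_hopping_landscape()
  fes <- exact_fes(hl, bins = 300)
  basins <- find_minima(fes, depth_cutoff = 2)
  expect_gte(length(basins), 3L)
  cen <- do.call(rbind, hopping_spec()$centers)
  for (k in 1:3) {
    d <- vapply(basins, function(b) sqrt(sum((b$location - cen[k, ])^2)),
                numeric(1))
    expect_lt(min(d), 0.15)
  }
  # member sets partition without overlap and contain their minima
  all_members <- unlist(lapply(basins, `[[`, "members"))
  expect_false(any(duplicated(all_members)))
  for (b in basins) expect_true(b$min_bin %in% b$members)
})

test_that("a monotone ramp has a single basin at its low end", {
  fes <- fes_grid(list(seq(0, 10, by = 0.1)), seq(0, 9.9, by = 0.1),
                  labels = "x")
  basins <- find_minima(fes)
  expect_length(basins, 1L)
  expect_lt(basins[[1]]$location, 0.2)
})

test_that("symmetric double well yields two equal-depth basins", {
  dw <- make_double_well(6, 4, 0)
  fes <- exact_fes(dw, bins = 400)
  basins <- find_minima(fes, depth_cutoff = 3)
  expect_length(basins, 2L)
  expect_lt(abs(basins[[1]]$fmin - basins[[2]]$fmin), 1e-9)
})

test_that("basin depth differences recover the generator offsets", {
  hl <- make_hopping_landscape()
  fes <- exact_fes(hl, bins = 300)
  basins <- find_minima(fes, depth_cutoff = 2)
  cen <- do.call(rbind, hopping_spec()$centers)
  pick <- function(k) {
    d <- vapply(basins, function(b) sum((b$location - cen[k, ])^2),
                numeric(1))
    basins[[which.min(d)]]
  }
  Aa <- pick(1); Ab <- pick(2); B <- pick(3)
  expect_equal(basin_delta_g(fes, Aa, Aa), 0)
  expect_equal(basin_delta_g(fes, Aa, Ab), 0.9, tolerance = 0.05)
  expect_equal(basin_delta_g(fes, Aa, B), 1.4, tolerance = 0.05)
})

test_that("integral-mode depth difference ignores uniform shifts", {
  dw <- make_double_well(6, 4, 0.9)
  make_shifted <- function(shift) {
    breaks <- seq(-4, 4, length.out = 401)
    ctr <- (breaks[-1] + breaks[-401]) / 2
    fes_grid(list(breaks), potential_energy(dw, cbind(ctr)) + shift,
             labels = "x", anchor = FALSE)
  }
  g0 <- {
    fes <- make_shifted(0)
    b <- find_minima(fes, depth_cutoff = 10)
    basin_delta_g(fes, b[[1]], b[[2]], mode = "integral")
  }
  g5 <- {
    fes <- make_shifted(5)
    b <- find_minima(fes, depth_cutoff = 15)
    basin_delta_g(fes, b[[1]], b[[2]], mode = "integral")
  }
  expect_equal(g0, g5, tolerance = 1e-10)
  # and it reproduces the quadrature population ratio
  kT <- kB * 300
  qL <- boltzmann_quadrature(dw, kT, region = list(c(-4, 0)))
  qR <- boltzmann_quadrature(dw, kT, region = list(c(0, 4)))
  expect_equal(abs(g0), abs(qR$free_energy - qL$free_energy),
               tolerance = 0.02)
})

test_that("barrier heights are read off by threshold flooding", {
  dw <- make_double_well(6, 4, 0)
  fes <- exact_fes(dw, bins = 800)
  basins <- find_minima(fes, depth_cutoff = 3)
  expect_equal(barrier_height(fes, basins[[1]], basins[[2]]), 6,
               tolerance = 0.02)
  expect_equal(barrier_height(fes, basins[[1]], basins[[1]]), 0)
  # hopping landscape: Ab -> Aa saddle relative to the higher minimum
  hl <- make_hopping_landscape()
  fes2 <- exact_fes(hl, bins = 400)
  b2 <- find_minima(fes2, depth_cutoff = 2)
  cen <- do.call(rbind, hopping_spec()$centers)
  pick <- function(k) {
    d <- vapply(b2, function(b) sum((b$location - cen[k, ])^2), numeric(1))
    b2[[which.min(d)]]
  }
  expect_equal(barrier_height(fes2, pick(2), pick(1)), 1.5,
               tolerance = 0.1)
  # disconnected visited regions are reported, not guessed
  v <- c(0, 1, NA, 1, 0.2)
  fes3 <- fes_grid(list(seq(0, 5)), v, labels = "x")
  b3 <- find_minima(fes3)
  expect_error(barrier_height(fes3, b3[[1]], b3[[2]]), "not connected")
})

test_that("flat-profile binding free energy is the width-ratio entropy", {
  kT <- kB * 300
  breaks <- seq(0, 28, by = 0.1)
  flat <- fes_grid(list(breaks), rep(0, length(breaks) - 1L), labels = "d")
  dg <- binding_delta_g(flat, binding_regions())
  expect_equal(dg$delta_g, -kT * log(7 / 2), tolerance = 1e-6)
  # unaligned bins: overlap weighting keeps the exact widths
  breaks2 <- seq(0, 28, by = 0.23)
  flat2 <- fes_grid(list(breaks2), rep(0, length(breaks2) - 1L),
                    labels = "d")
  dg2 <- binding_delta_g(flat2, binding_regions())
  expect_equal(dg2$delta_g, -kT * log(7 / 2), tolerance = 1e-6)
})

test_that("binding free energy is gauge-invariant and mode-consistent", {
  kT <- kB * 300
  breaks <- seq(0, 28, by = 0.1)
  ctr <- (breaks[-1] + breaks[-length(breaks)]) / 2
  f <- ifelse(ctr >= 7 & ctr <= 14, 0, 5)   # deep square well on bound
  fes <- fes_grid(list(breaks), f, labels = "d", anchor = FALSE)
  dg <- binding_delta_g(fes, binding_regions())$delta_g
  expect_equal(dg, -5 - kT * log(7 / 2), tolerance = 0.02)
  fes_s <- fes_grid(list(breaks), f + 3, labels = "d", anchor = FALSE)
  expect_equal(binding_delta_g(fes_s, binding_regions())$delta_g, dg,
               tolerance = 1e-10)
  dgm <- binding_delta_g(fes, binding_regions(), mode = "minimum")
  expect_equal(dgm$delta_g, -5)
  # standard-state correction only on request
  dgc <- binding_delta_g(fes, binding_regions(), standard_state = TRUE,
                         unbound_volume = 1661)
  expect_equal(dgc$delta_g, dg, tolerance = 1e-10)
  # empty overlap errors name the offending region
  short <- fes_grid(list(seq(0, 20, by = 0.1)), rep(0, 200), labels = "d")
  expect_error(binding_delta_g(short, binding_regions()), "unbound")
})

test_that("recrossing counting collapses repeated visits", {
  r <- binding_regions()
  d <- c(10, 11, 12, 25, 25.5, 10, 9, 25, 10, 25)  # 5 crossings
  expect_equal(count_recrossings(c(10, 18, 10, 18, 10), r), 0L)
  expect_equal(count_recrossings(d, r), 5L)
  expect_equal(count_recrossings(rep(18, 5), r), 0L)
})

test_that("convergence profile starts at the flat-surface value", {
  wt <- wt_params(widths = 0.23, grid_min = 0, grid_max = 28,
                  grid_bins = 281)
  b <- new_bias_state(wt, labels = "d")
  deposit(b, 10, t = 1, params = wt)
  deposit(b, 12, t = 2, params = wt)
  conv <- convergence_profile(b, c(0, 1, 2), binding_regions())
  kT <- kB * 300
  expect_equal(conv$profile$delta_g[1], -kT * log(7 / 2),
               tolerance = 1e-6)
  # hills dropped in the bound well deepen its apparent free energy
  expect_lt(conv$profile$delta_g[3], conv$profile$delta_g[1])
})

test_that("a converged toy binding run settles its dG(t) profile", {
  # compact 1D binding landscape: a 4 kcal/mol well inside the bound
  # region, flat solvent plateau out to an upper wall; a gentle bias
  # factor keeps the well-tempered transient short
  well <- function(x) -4 * exp(-(x - 5)^2 / (2 * 1.2^2))
  pot <- analytic_potential(
    energy = function(X) well(X[, 1]) - well(12),
    gradient = function(X)
      cbind(4 * (X[, 1] - 5) / 1.2^2 * exp(-(X[, 1] - 5)^2 / (2 * 1.2^2))),
    bounds = matrix(c(2, 13.5), 1), labels = "d")
  reg <- binding_regions(bound = c(4, 7), unbound = c(10, 12))
  wt <- wt_params(delta_t = 900, grid_min = 2, grid_max = 13.5)
  res <- run_metadynamics(pot, wt, langevin_params(nsteps = 6e5, seed = 17,
                                                   friction = 15),
                          walls = list(wall_spec("d", 13, 10)), x0 = 5)
  H <- hills_matrix(res$bias)
  conv <- convergence_profile(res$bias, seq(0, max(H[, 1]),
                                            length.out = 60),
                              reg, trajectory = res$trajectory)
  expect_gt(conv$recrossings, 4)
  tail_q <- conv$profile$delta_g[conv$profile$time >=
                                   0.75 * max(conv$profile$time)]
  expect_lt(diff(range(tail_q)), 0.5)
  # and the settled value agrees with the quadrature oracle
  kT <- kB * 300
  qb <- boltzmann_quadrature(pot, kT, region = list(reg$bound))
  qu <- boltzmann_quadrature(pot, kT, region = list(reg$unbound))
  expect_equal(tail_q[length(tail_q)],
               qb$free_energy - qu$free_energy, tolerance = 0.5)
})

test_that("block standard error of dG behaves like a sample SE", {
  # construct a trajectory whose four blocks are literally identical
  x <- c(seq(8, 13, by = 0.5), seq(24.2, 25.8, by = 0.4))
  xs <- rep(x, 4)
  tr <- cv_trajectory(seq_along(xs), matrix(xs, ncol = 1,
                                            dimnames = list(NULL, "d")))
  w <- rep(1 / length(xs), length(xs))
  se <- delta_g_uncertainty(tr, w, binding_regions(), n_blocks = 4,
                            breaks = seq(0, 28, by = 0.5))
  expect_equal(se, 0, tolerance = 1e-10)
  expect_gte(se, 0)
  # two blocks differing by a known amount: SE is half their spread
  x1 <- c(rep(10, 40), rep(25, 10))
  x2 <- c(rep(10, 20), rep(25, 30))
  tr2 <- cv_trajectory(seq_len(100), matrix(c(x1, x2), ncol = 1,
                                            dimnames = list(NULL, "d")))
  w2 <- rep(1 / 100, 100)
  se2 <- delta_g_uncertainty(tr2, w2, binding_regions(), n_blocks = 2,
                             breaks = seq(0, 28, by = 0.5))
  kT <- kB * 300
  dg1 <- -kT * log(40 / 10)
  dg2 <- -kT * log(20 / 30)
  expect_equal(se2, abs(dg1 - dg2) / 2, tolerance = 1e-9)
})
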