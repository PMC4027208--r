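test_that("double well pins minima, gap and stationarity by construction", {
  dw0 <- make_double_well(6, 4, 0)
  expect_equal(potential_energy(dw0, -2), potential_energy(dw0, 2))
  dw <- make_double_well(6, 4, 0.9)
  e <- potential_energy(dw, rbind(-2, 2))
  expect_equal(e[2] - e[1], 0.9, tolerance = 1e-8)
  expect_lt(max(abs(potential_gradient(dw, rbind(-2, 2)))), 1e-6)
  # exactly two local minima, `separation` apart (grid search oracle)
  xs <- seq(-4, 4, length.out = 4001)
  v <- potential_energy(dw, cbind(xs))
  is_min <- which(v[2:4000] < v[1:3999] & v[2:4000] < v[3:4001]) + 1L
  expect_length(is_min, 2L)
  expect_equal(diff(xs[is_min]), 4, tolerance = 1e-2)
  expect_error(make_double_well(-1, 4), "positive")
  expect_error(make_double_well(6, 0), "positive")
})

test_that("analytic gradients match central finite differences", {
  pots <- list(make_double_well(6, 4, 0.9), make_hopping_landscape())
  for (pot in pots) {
    set.seed(7)
    X <- sapply(seq_len(pot$dim), function(i)
      runif(100, pot$bounds[i, 1], pot$bounds[i, 2]))
    X <- matrix(X, ncol = pot$dim)
    h <- 1e-5 * (pot$bounds[, 2] - pot$bounds[, 1])
    g <- potential_gradient(pot, X)
    gfd <- fd_gradient(pot, X, h)
    scale <- pmax(abs(gfd), 1e-3)
    expect_lt(max(abs(g - gfd) / scale), 1e-5)
    expect_true(all(is.finite(potential_energy(pot, X))))
  }
})

test_that("hopping landscape recovers its specified centers and offsets", {
  hl <- make_hopping_landscape()
  spec <- hopping_spec()
  cen <- do.call(rbind, spec$centers)
  # calibrated minima sit on the requested centers at the requested depths
  for (k in 1:3) {
    opt <- optim(cen[k, ], function(p) potential_energy(hl, rbind(p)),
                 method = "BFGS", control = list(reltol = 1e-12))
    expect_lt(sqrt(sum((opt$par - cen[k, ])^2)), 0.1)
    expect_equal(opt$value, c(0, 0.9, 1.4)[k], tolerance = 0.05)
  }
})

test_that("hopping landscape saddle matches the requested barrier", {
  # flood-fill threshold search on a 500 x 500 grid of the exact surface
  hl <- make_hopping_landscape()
  fes <- exact_fes(hl, bins = 500)
  basins <- find_minima(fes, depth_cutoff = 2)
  cen <- do.call(rbind, hopping_spec()$centers)
  pick <- function(target) {
    d2 <- vapply(basins, function(b) sum((b$location - target)^2), numeric(1))
    basins[[which.min(d2)]]
  }
  barrier <- barrier_height(fes, pick(cen[2, ]), pick(cen[1, ]))
  expect_equal(barrier, 1.5, tolerance = 0.1)
})

test_that("degenerate hopping spec gives symmetric equal-depth minima", {
  # zero offsets and equal channel barriers make Aa and B mirror images
  # through Ab's vertical axis: their minima and basin masses coincide
  hl <- make_hopping_landscape(hopping_spec(offsets = c(Ab = 0, B = 0),
                                            barrier = 1.5,
                                            barrier_ab_b = 1.5))
  kT <- kB * 300
  cen <- do.call(rbind, hopping_spec()$centers)
  emin <- vapply(1:3, function(k)
    optim(cen[k, ], function(p) potential_energy(hl, rbind(p)),
          method = "BFGS", control = list(reltol = 1e-12))$value,
    numeric(1))
  expect_lt(abs(emin[3] - emin[1]), 1e-9)  # exact mirror pair
  expect_lt(diff(range(emin)), 1e-4)       # calibration precision for Ab
  masses <- vapply(1:3, function(k) {
    boltzmann_quadrature(hl, kT, region = list(cen[k, 1] + c(-2, 2),
                                               cen[k, 2] + c(-2, 2)),
                         n = 301)$mass
  }, numeric(1))
  expect_lt(abs(masses[3] / masses[1] - 1), 1e-6)  # exact mirror pair
  # Ab sits between two channels, so its basin mass differs only mildly
  expect_lt(abs(masses[2] / masses[1] - 1), 0.3)
})

test_that("hopping spec validation rejects bad geometry and offsets", {
  expect_error(hopping_spec(offsets = c(Ab = -0.1, B = 1)), "offsets")
  expect_error(hopping_spec(barrier = 0.5), "barrier")
  expect_error(
    hopping_spec(centers = list(Aa = c(0, 0), Ab = c(1, 0), B = c(8, 0))),
    "overlap")
})

test_that("Boltzmann quadrature reproduces the Gaussian integral", {
  kT <- kB * 300
  hw <- make_harmonic(k = 2, halfwidth = 8)
  q <- boltzmann_quadrature(hw, kT, n = 1601)
  expect_equal(q$mass, sqrt(2 * pi * kT / 2), tolerance = 1e-6)
  # doubling the resolution moves the result by < 1e-6 relative
  q2 <- boltzmann_quadrature(hw, kT, n = 3201)
  expect_lt(abs(q2$mass - q$mass) / q$mass, 1e-6)
})

test_that("quadrature free-energy differences recover the built-in gap", {
  kT <- 0.596
  dws <- make_double_well(6, 4, 0)
  qL <- boltzmann_quadrature(dws, kT, region = list(c(-4, 0)))
  qR <- boltzmann_quadrature(dws, kT, region = list(c(0, 4)))
  expect_equal(qL$mass, qR$mass, tolerance = 1e-10)
  dwa <- make_double_well(6, 4, 0.9)
  qL <- boltzmann_quadrature(dwa, kT, region = list(c(-4, 0)))
  qR <- boltzmann_quadrature(dwa, kT, region = list(c(0, 4)))
  expect_equal(qR$free_energy - qL$free_energy, 0.9, tolerance = 0.02)
  expect_error(boltzmann_quadrature(dwa, kT, region = list(c(2, 2))),
               "empty|invalid")
})

test_that("quadrature marginal profile matches a hand-built marginal", {
  hl <- make_hopping_landscape()
  kT <- kB * 300
  breaks <- seq(-3, 4.5, by = 0.5)
  qm <- quadrature_marginal_fes(hl, kT, axis = 2, breaks = breaks)
  # independent oracle: trapezoid 2D Boltzmann sums per bin
  nx <- 800
  xs <- seq(hl$bounds[1, 1], hl$bounds[1, 2], length.out = nx)
  wx <- rep(1, nx); wx[c(1, nx)] <- 0.5
  mass <- vapply(seq_len(length(breaks) - 1L), function(b) {
    ys <- seq(breaks[b], breaks[b + 1], length.out = 60)
    wy <- rep(1, 60); wy[c(1, 60)] <- 0.5
    X <- cbind(rep(xs, times = 60), rep(ys, each = nx))
    W <- rep(wx, times = 60) * rep(wy, each = nx)
    sum(W * exp(-potential_energy(hl, X) / kT))
  }, numeric(1))
  f <- -kT * log(mass / sum(mass))
  f <- f - min(f)
  expect_lt(max(abs(qm$values - f)), 0.02)
})
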