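test_that("angular quadratures integrate exactly and match the Newton
           oracle", {
  q2 <- make_quadrature(2)
  expect_equal(sort(q2$mu), c(-1, 1) / sqrt(3), tolerance = 1e-14)
  for (N in c(2, 16, 48)) {
    q <- make_quadrature(N)
    expect_equal(sum(q$w), 2, tolerance = 1e-12)
    expect_equal(sort(q$mu), sort(-q$mu), tolerance = 1e-13)  # +/- pairs
    expect_true(all(q$mu != 0))
  }
  ## independent oracle: Newton iteration on P_N with the recurrence coded
  ## here from scratch
  legP <- function(n, x) {
    p0 <- rep(1, length(x)); p1 <- x
    for (k in 2:n) { p <- ((2 * k - 1) * x * p1 - (k - 1) * p0) / k
      p0 <- p1; p1 <- p }
    list(p = p1, pm = p0)
  }
  N <- 48
  x <- cos(pi * (4 * (1:N) - 1) / (4 * N + 2))
  for (i in 1:100) {
    l <- legP(N, x)
    dp <- N * (x * l$p - l$pm) / (x^2 - 1)
    x <- x - l$p / dp
  }
  expect_equal(sort(make_quadrature(48)$mu), sort(x), tolerance = 1e-13)
  expect_error(make_quadrature(7), "even")
})

test_that("slab geometry and beam source validate their inputs", {
  expect_error(slab_geometry(c(0, 1, 0.5), "water"), "increasing")
  expect_error(beam_source(25), "MeV")
  expect_error(beam_source(1, Q = 0), "positive")
  g <- slab_geometry(seq(0, 1, 0.1), "water")
  expect_equal(g$nvox, 10)
  expect_equal(g$mid[1], 0.05)
})

test_that("the scattering source matches a direct double-sum oracle", {
  ## hand-built random miniature library
  set.seed(11)
  N <- 4; L <- 2; nvox <- 3
  S <- array(0, c(L + 1, N, N))
  for (g in 1:N) for (gp in g:N) S[, g, gp] <- runif(L + 1, 0, 0.3)
  lib <- list(groups = make_groups(1, N, spacing = "linear"), L = L,
              mat = list(water = list(S = S,
                material = nist_material("water"))))
  geom <- slab_geometry(seq(0, 0.3, 0.1), "water")
  phi <- array(runif((L + 1) * N * nvox), c(L + 1, N, nvox))
  quad <- make_quadrature(4)
  got <- scattering_source(phi, lib, geom, g = 3, quad)
  for (n in 1:4) for (v in 1:nvox) {
    s <- 0
    for (l in 0:L) for (gp in 1:3) {
      Pl <- bfpdose:::.legendre_all(quad$mu[n], l)[l + 1, 1]
      s <- s + (2 * l + 1) / 2 * Pl * S[l + 1, gp, 3] * phi[l + 1, gp, v]
    }
    expect_equal(got[n, v], s, tolerance = 1e-12)
  }
})

test_that("slowing-down coupling is conservative: removal equals the
           downstream source", {
  gs <- make_groups(1.0, 20)
  lib <- assemble_library("water", gs, L = 2, channels = character(0))
  geom <- slab_geometry(seq(0, 0.6, length.out = 61), "water")
  csd <- csd_coupling(lib, geom)
  blo <- bfpdose:::.beta_edge_vox(lib, geom)
  expect_equal(csd, blo / gs$dE, tolerance = 1e-14)
  ## particle ledger on a pure-CSD solve with the step closure: every
  ## injected electron eventually crosses the cutoff inside the slab
  src <- beam_source(1.0)
  sol <- solve_bfp(geom, lib, src, sn = 4, energy_closure = "step")
  crossings <- sum(sol$below_cutoff_rate * geom$dx)
  expect_equal(crossings + sol$leak_particles, src$Q, tolerance = 1e-6)
  ## beta = 0 leaves the operator inert
  lib0 <- lib
  lib0$mat$water$beta_lo <- rep(0, gs$N)
  expect_true(all(csd_coupling(lib0, geom) == 0))
})

test_that("the transport sweep reproduces exponential attenuation at
           second order", {
  quad <- make_quadrature(2)
  sig0 <- 5
  err_at <- function(nc) {
    dx <- rep(1 / nc, nc)
    q <- matrix(0, 2, nc)
    inc <- c(0, 1)                      # unit flux on the +mu direction
    sw <- sweep_slab(quad, rep(sig0, nc), dx, q, inc_left = inc)
    mu <- quad$mu[2]
    x <- cumsum(dx) - dx / 2
    ref <- mu / (sig0 * dx) * exp(-sig0 * (x - dx / 2) / mu) *
      (1 - exp(-sig0 * dx / mu))        # exact cell average
    max(abs(sw$psi[2, ] - ref) / ref[1])
  }
  e1 <- err_at(20); e2 <- err_at(40); e3 <- err_at(80)
  expect_gt(e1 / e2, 3.5)               # ~4x per halving: 2nd order
  expect_gt(e2 / e3, 3.5)
  ## sigma = 0, no source: flux constant along the direction
  sw0 <- sweep_slab(quad, rep(0, 10), rep(0.1, 10), matrix(0, 2, 10),
                    inc_left = c(0, 2))
  expect_equal(sw0$psi[2, ], rep(2, 10), tolerance = 1e-14)
  expect_equal(sw0$out_right[2], 2)
  ## vacuum right boundary: nothing comes back on -mu directions
  expect_true(all(sw0$psi[1, ] == 0))
})

test_that("pure continuous-slowing-down transport reproduces the analytic
           CSDA depth-dose", {
  w <- fix_water()
  gs <- make_groups(1.0, 150)
  lib <- assemble_library("water", gs, L = 2, channels = character(0))
  geom <- slab_geometry(seq(0, csda_range(w, 1.0), length.out = 201),
                        "water")
  src <- beam_source(1.0)
  sol <- solve_bfp(geom, lib, src, sn = 8, beam = "first-collision")
  dd <- dose_profile(sol, lib, geom, src)
  ## independent ODE oracle: integrate dE/dx = -S and evaluate S(E(x))
  Eg <- exp(seq(log(1), log(0.001), length.out = 4000))
  S <- collision_sp(w, Eg) + radiative_sp(w, Eg)
  x_of_E <- c(0, cumsum(-diff(Eg) / ((S[-1] + S[-4000]) / 2)))
  E_of_x <- stats::approxfun(x_of_E, Eg, rule = 2)
  ee <- E_of_x(geom$edges)
  ee[geom$edges >= max(x_of_E)] <- 0.001
  Dan <- -diff(ee) / geom$dx            # voxel-averaged analytic dose
  err <- abs(dd$dose - Dan) / max(Dan[1:200])
  expect_lt(max(err[1:199]), 0.01)      # <1% everywhere but the last voxel
})

test_that("inner iterations honour the requested tolerance", {
  lib <- fix_lib_small()
  geom <- slab_geometry(seq(0, 0.44, length.out = 41), "water")
  src <- beam_source(1.0)
  sol <- solve_bfp(geom, lib, src, sn = 8, tol = 1e-5)
  expect_true(all(sol$residuals <= 1e-5))
  expect_true(all(sol$iterations >= 1))
})

test_that("the two dose routes agree to rounding and zero flux gives zero
           dose", {
  lib <- fix_lib_small()
  geom <- slab_geometry(seq(0, 0.44, length.out = 41), "water")
  src <- beam_source(1.0)
  sol <- solve_bfp(geom, lib, src, sn = 8)
  d1 <- dose_profile(sol, lib, geom, src, route = "deposition")
  d2 <- dose_profile(sol, lib, geom, src, route = "direct")
  expect_equal(d1$dose, d2$dose, tolerance = 1e-8)
  sol0 <- sol
  sol0$phi[] <- 0
  sol0$below_cutoff_rate[] <- 0
  expect_true(all(dose_profile(sol0, lib, geom, src)$dose == 0))
  ## density override scales like mass thickness
  geom2 <- slab_geometry(seq(0, 0.22, length.out = 41), "water",
                         rho = rep(2, 40))
  sol2 <- solve_bfp(geom2, lib, src, sn = 8)
  d3 <- dose_profile(sol2, lib, geom2, src)
  expect_equal(d3$dose[1] , d1$dose[1], tolerance = 0.02)
})

test_that("angular refinement stabilises the solution", {
  lib <- fix_lib_small()
  geom <- slab_geometry(seq(0, 0.44, length.out = 41), "water")
  src <- beam_source(1.0)
  d <- lapply(c(8, 16, 32), function(n) {
    dose_profile(solve_bfp(geom, lib, src, sn = n,
                           beam = "first-collision"), lib, geom, src)$dose
  })
  ch1 <- max(abs(d[[2]] - d[[1]])) / max(d[[1]])
  ch2 <- max(abs(d[[3]] - d[[2]])) / max(d[[2]])
  expect_lt(ch2, ch1)                   # monotone stabilisation
})
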