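test_that("collisional stopping power matches an independent Bethe coding
           for water (I = 75 eV)", {
  w <- fix_water()
  ## independent re-coding of the Bethe formula with Sternheimer delta
  bethe <- function(E) {
    me <- 0.51099895
    tau <- E / me
    g <- tau + 1
    b2 <- 1 - 1 / g^2
    I <- 75e-6
    za <- sum(w$mass_fractions *
                vapply(w$elements, `[[`, numeric(1), "Z") /
                vapply(w$elements, `[[`, numeric(1), "A"))
    hwp <- 28.8159 * sqrt(1.0 * za) * 1e-6        # plasma energy [MeV]
    Cbar <- 2 * log(I / hwp) + 1
    x <- log10(sqrt(tau * (tau + 2)))
    x0 <- if (Cbar < 3.681) 0.2 else 0.326 * Cbar - 1.0
    x1 <- 2
    aa <- (Cbar - 4.606 * x0) / (x1 - x0)^3
    d <- if (x >= x1) 4.606 * x - Cbar else
      if (x >= x0) 4.606 * x - Cbar + aa * (x1 - x)^3 else 0
    d <- max(d, 0)
    Ft <- 1 - b2 + (tau^2 / 8 - (2 * tau + 1) * log(2)) / (tau + 1)^2
    0.1535374 * za / b2 * (log(tau^2 * (tau + 2) / (2 * (I / me)^2)) + Ft - d)
  }
  expect_equal(collision_sp(w, 1.0), bethe(1.0), tolerance = 1e-9)
  expect_equal(collision_sp(w, 0.05), bethe(0.05), tolerance = 1e-9)
})

test_that("the sub-10-keV power law joins the Bethe branch continuously", {
  w <- fix_water()
  lo <- collision_sp(w, 0.01 * (1 - 1e-9))
  hi <- collision_sp(w, 0.01)
  expect_equal(lo, hi, tolerance = 1e-7)
  expect_error(collision_sp(w, 5e-4), "cutoff")
})

test_that("the density effect reduces the collisional stopping power", {
  w <- fix_water()
  expect_gt(collision_sp(w, 20, density_effect = FALSE),
            collision_sp(w, 20, density_effect = TRUE))
  ## delta nonnegative and nondecreasing above 1 MeV
  E <- seq(1, 20, length.out = 40)
  d <- bfpdose:::.sternheimer_delta(w, E)
  expect_true(all(d >= 0))
  expect_true(all(diff(d) >= 0))
})

test_that("radiative stopping power equals the quadrature oracle and scales
           with Z", {
  w <- fix_water()
  or <- stats::integrate(function(k) {
    s <- 0
    for (sym in names(w$atom_density)) {
      s <- s + w$atom_density[[sym]] *
        brems_dcs(1.0, k, w$elements[[sym]]$Z)
    }
    k * s * 1e-24
  }, 0.001, 1.0 - 0.001, rel.tol = 1e-10)$value
  expect_equal(radiative_sp(w, 1.0), or, tolerance = 1e-7)
  au <- nist_material("gold")
  expect_gt(radiative_sp(au, 20) / collision_sp(au, 20),
            10 * radiative_sp(w, 20) / collision_sp(w, 20))
  ## domain vanishes at twice the cutoff
  expect_equal(radiative_sp(w, 0.002), 0)
})

test_that("restricted stopping powers obey beta + M = S and collapse to S
           when the catastrophic domain is empty", {
  w <- fix_water()
  gs <- make_groups(1.0, 30)
  for (g in c(1, 10, 25)) {
    b <- restricted_sp(w, g, gs)
    t <- bfpdose:::.soft_threshold(gs, g)
    eb <- c(gs$boundaries[g], gs$boundaries[g + 1])
    mc <- mean(vapply(eb, function(e)
      bfpdose:::.cat_moment_coll(w, e, t), numeric(1)))
    sc <- mean(collision_sp(w, eb))
    expect_equal(b[["beta_c"]] + mc, sc, tolerance = 1e-12)
    expect_lte(b[["beta_c"]], sc)
    expect_gte(b[["beta_c"]], 0)
  }
  ## catastrophic transfers need sinks two groups down: for the second
  ## group of a 3-group structure the threshold saturates at the cutoff,
  ## the domain [E - t, E/2] is empty, and beta = S exactly
  gs3 <- make_groups(1.0, 3, spacing = "linear")
  b3 <- restricted_sp(w, 2, gs3)
  expect_equal(b3[["beta_c"]],
               mean(collision_sp(w, gs3$boundaries[2:3])),
               tolerance = 1e-12)
})

test_that("catastrophic first moment matches fine-grid integration on a
           coarse toy structure", {
  w <- fix_water()
  E <- 0.9; t <- 0.55                   # wide catastrophic domain
  ne_mass <- 6.02214076e23 * w$ZA_eff
  oracle <- trap(function(W) W * moller_dcs(E, W) * ne_mass * 1e-24,
                 E - t, E / 2, n = 2e5)
  expect_equal(bfpdose:::.cat_moment_coll(w, E, t), oracle,
               tolerance = 1e-6)
})

test_that("restricted momentum transfer matches a fine-quadrature oracle,
           vanishes with the domain, and falls with energy", {
  w <- fix_water()
  gs <- make_groups(1.0, 10)
  a10 <- momentum_transfer(w, 1, gs)
  ## oracle: trapezoid in the forward sliver [0.999999, 1]
  orc <- function(E) {
    tot <- 0
    for (sym in names(w$atom_density)) {
      Z <- w$elements[[sym]]$Z
      mu <- seq(0.999999, 1, length.out = 2e5)
      v <- elastic_dcs(E, mu, Z, mott = FALSE) * (1 - mu)
      tot <- tot + w$atom_density[[sym]] * 1e-24 *
        sum((v[-1] + v[-2e5]) / 2 * diff(mu))
    }
    tot / w$rho
  }
  eb <- c(gs$boundaries[1], gs$boundaries[2])
  expect_equal(a10, mean(vapply(eb, orc, numeric(1))), tolerance = 1e-6)
  expect_equal(momentum_transfer(w, 1, gs, mu_star = 1), 0)
  av <- vapply(1:10, function(g) momentum_transfer(w, g, gs), numeric(1))
  expect_true(all(av > 0))
  ## on the fixed forward sliver, eta^2 in the denominator outgrows the
  ## Rutherford prefactor as the energy falls, so alpha shrinks toward
  ## low energies (group 1 = highest energy)
  expect_true(all(diff(av) < 0))
})

test_that("beta never exceeds S for catalogue materials and the CSDA range
           is strictly increasing", {
  gs <- make_groups(5.0, 12)
  for (nm in c("water", "cortical bone", "gold")) {
    m <- nist_material(nm)
    for (g in c(1, 6, 11)) {
      b <- restricted_sp(m, g, gs)
      eb <- c(gs$boundaries[g], gs$boundaries[g + 1])
      expect_lte(b[["beta_c"]], mean(collision_sp(m, eb)) + 1e-12)
      expect_lte(b[["beta_b"]], mean(radiative_sp(m, eb)) + 1e-12)
    }
  }
  w <- fix_water()
  E0 <- c(0.01, 0.1, 1, 5, 20)
  r <- vapply(E0, function(e) csda_range(w, e), numeric(1))
  expect_true(all(diff(r) > 0))
})
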