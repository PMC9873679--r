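test_that("group structures have the required shape", {
  g3 <- make_groups(1.0, 3, spacing = "linear")
  expect_length(g3$boundaries, 4)
  expect_identical(g3$boundaries[4], 0.001)
  expect_identical(g3$boundaries[1], 1.0)
  glog <- make_groups(2.0, 25)
  r <- glog$boundaries[-26] / glog$boundaries[-1]
  expect_equal(max(r) / min(r), 1, tolerance = 1e-12)
  ## the benchmark configuration of the full-scale runs
  gbig <- make_groups(20, 300)
  expect_equal(gbig$N, 300)
  expect_identical(gbig$boundaries[1], 20)
  expect_true(all(diff(gbig$boundaries) < 0))
  expect_error(make_groups(5e-4, 10), "cutoff")
  expect_error(make_groups(1, 2), "3 groups")
  expect_error(make_groups(30, 10), "20 MeV")
})

test_that("ionization feeds balance: one primary and one delta per event", {
  lib <- fix_lib_small()
  gs <- lib$groups
  ion <- ionization_feed(fix_water(), gs, L = 3)
  see <- rowSums(ion$F0_ee[1, , ])
  sed <- rowSums(ion$F0_ed[1, , ])
  nz <- see > 0
  expect_true(any(nz))
  expect_lt(max(abs(see[nz] - sed[nz]) / see[nz]), 1e-10)
  expect_lt(max(abs(see[nz] - ion$T[nz]) / see[nz]), 1e-10)
})

test_that("delta rays sink below E/2 and primaries above", {
  gs <- make_groups(1.0, 24)
  ion <- ionization_feed(fix_water(), gs, L = 1)
  b <- gs$boundaries
  for (g in seq_len(gs$N)) {
    ed <- which(ion$F0_ed[1, g, 1:gs$N] > 0)
    ee <- which(ion$F0_ee[1, g, 1:gs$N] > 0)
    ## delta sinks lie entirely below half the group's top energy
    if (length(ed)) expect_true(all(b[ed + 1] < b[g] / 2))
    ## primary sinks reach at least half the group's bottom energy
    if (length(ee)) expect_true(all(b[ee] > b[g + 1] / 2))
  }
})

test_that("ionization transfer entries match brute-force integration on a
           coarse structure", {
  ## the coarsest structure with a non-empty catastrophic domain (with
  ## non-adjacent down-scatter, sinks need b[g+2] > E/2)
  gs <- make_groups(1.0, 24)
  w <- fix_water()
  ion <- ionization_feed(w, gs, L = 3)
  ne <- w$electron_density * 1e-24
  b <- gs$boundaries
  g <- 1
  t <- b[3]
  ## flat-flux source average by fine trapezoid (domain kinks placed on
  ## grid nodes), sinks by fine trapezoid
  kinks <- c(2 * b, t + b)
  Egrid <- sort(unique(c(seq(b[g + 1], b[g], length.out = 2000),
                         kinks[kinks > b[g + 1] & kinks < b[g]])))
  nE <- length(Egrid)
  brute <- function(lo_of, hi_of, wgt_of, l, m) {
    vals <- vapply(Egrid, function(E) {
      Wc <- max(E - t, 0.001)
      lo <- lo_of(E, Wc); hi <- hi_of(E, Wc)
      if (hi <= lo) return(0)
      x <- seq(lo, hi, length.out = 5000)
      sig <- bfpdose:::.moller_dcs_raw(E, wgt_of(E, x))
      mu <- moller_mu(E, x)
      P <- bfpdose:::.legendre_all(mu, l)[l + 1, ]
      v <- sig * P * x^m
      sum((v[-1] + v[-5000]) / 2 * diff(x))
    }, numeric(1))
    sum((vals[-1] + vals[-nE]) / 2 * diff(Egrid)) / (b[g] - b[g + 1]) * ne
  }
  for (gp in which(ion$F0_ed[1, g, 1:24] > 0)) {
    for (l in c(0, 2)) {
      ## delta branch into sink group gp: W in [Wc, E/2] clipped to group
      got0 <- ion$F0_ed[l + 1, g, gp]
      or0 <- brute(function(E, Wc) max(b[gp + 1], Wc),
                   function(E, Wc) min(b[gp], E / 2),
                   function(E, x) x, l, 0)
      expect_equal(got0, or0, tolerance = 1e-6)
    }
    or1 <- brute(function(E, Wc) max(b[gp + 1], Wc),
                 function(E, Wc) min(b[gp], E / 2),
                 function(E, x) x, 0, 1)
    expect_equal(ion$F1_ed[1, g, gp], or1, tolerance = 1e-6)
  }
  ## primary branch entries (E' in [E/2, E - Wc], kernel at W = E - E')
  for (gp in which(ion$F0_ee[1, g, 1:24] > 0)) {
    or0 <- brute(function(E, Wc) max(b[gp + 1], E / 2),
                 function(E, Wc) min(b[gp], E - Wc),
                 function(E, x) E - x, 0, 0)
    expect_equal(ion$F0_ee[1, g, gp], or0, tolerance = 1e-6)
  }
})

test_that("bremsstrahlung transfers are Legendre-order independent and
           vanish when the photon window closes", {
  gs <- make_groups(1.0, 12)
  lib <- assemble_library("water", gs, L = 4, channels = "brems")
  m <- lib$mat$water
  for (l in 1:4) {
    expect_identical(m$S[l + 1, , ], m$S[1, , ])   # forward Dirac kernel
  }
  br <- brems_feed(fix_water(), gs)
  ## lowest group: E < 2 keV leaves no room between the 1 keV photon
  ## cutoff and the 1 keV electron cutoff
  expect_identical(br$T[12], 0)
  expect_true(all(br$F0 >= 0))
  expect_true(all(br$R >= 0))
})

test_that("bremsstrahlung entries match brute-force integration on a
           3-group toy", {
  gs <- fix_gs3()
  w <- fix_water()
  br <- brems_feed(w, gs)
  b <- gs$boundaries
  g <- 1; t <- b[3]
  sig_mac <- function(E, k) {
    s <- 0
    for (sym in names(w$atom_density)) {
      s <- s + w$atom_density[[sym]] * 1e-24 *
        brems_dcs(E, k, w$elements[[sym]]$Z)
    }
    s
  }
  ## log-spaced source grid (the integrand steepens like a power law
  ## toward the lower boundary), kinks on grid nodes, log-spaced sinks
  ## (the cross section steepens toward the spectrum tip)
  kinks <- c(2 * b, t + b, t + 0.001)
  Egrid <- sort(unique(c(exp(seq(log(b[2]), log(b[1]),
                                 length.out = 4000)),
                         kinks[kinks > b[2] & kinks < b[1]])))
  nE <- length(Egrid)
  for (gp in which(br$F0[g, 1:3] > 0)) {
    vals <- vapply(Egrid, function(E) {
      kc <- max(E - t, 0.001)
      lo <- max(b[gp + 1], 0.001)            # electron residual E'
      hi <- min(b[gp], E - kc)
      hi <- min(hi, E - 0.001)
      if (hi <= lo) return(0)
      u <- seq(log(lo), log(hi), length.out = 4000)
      x <- exp(u)
      v <- sig_mac(E, E - x) * x
      sum((v[-1] + v[-4000]) / 2 * diff(u))
    }, numeric(1)) * Egrid
    lE <- log(Egrid)
    or <- sum((vals[-1] + vals[-nE]) / 2 * diff(lE)) / (b[1] - b[2])
    expect_equal(br$F0[g, gp], or, tolerance = 1e-6)
  }
})

test_that("elastic moments: transport correction zeroes the order-L moment,
           moments are bounded by the total, and match a fine-grid oracle", {
  gs <- make_groups(1.0, 8)
  al <- nist_material("aluminium")
  el <- elastic_feed(al, gs, L = 5)
  expect_true(all(el$F_corr[6, ] == 0))
  for (g in 1:8) {
    expect_true(all(abs(el$F[, g]) <= el$F[1, g] * (1 + 1e-12)))
  }
  ## fine-grid oracle for group 3: log-spaced grid in (a - mu) resolves the
  ## screening peak; source average over the same flat-flux weighting
  g <- 3
  src <- bfpdose:::.src_nodes(gs, g)
  Z <- 13
  nd <- al$atom_density[["Al"]] * 1e-24
  for (l in c(0, 3)) {
    or <- 0
    for (i in seq_along(src$E)) {
      E <- src$E[i]
      eta <- moliere_eta(E, Z)
      a <- 1 + 2 * eta
      u <- exp(seq(log(a - 0.999999), log(a + 1), length.out = 1e5))
      mu <- pmin(pmax(a - u, -1), 1)
      v <- elastic_dcs(E, mu, Z) *
        bfpdose:::.legendre_all(mu, l)[l + 1, ] * u
      lu <- log(u)
      or <- or + src$w[i] * nd * sum((v[-1] + v[-1e5]) / 2 * diff(lu))
    }
    expect_equal(el$F[l + 1, g], or, tolerance = 1e-7)
  }
})

test_that("Auger production is isotropic, respects the cutoff, and lands in
           the right group", {
  gs <- make_groups(1.0, 30)
  ## water: O and H Auger lines sit below the 1 keV cutoff
  relw <- relaxation_feed(fix_water(), gs)
  expect_true(all(relw$F0 == 0))
  expect_gt(relw$n_subcutoff, 0)
  ## aluminium: K-shell Auger at ~1.41 keV enters the lowest groups
  al <- nist_material("aluminium")
  rel <- relaxation_feed(al, gs)
  expect_gt(sum(rel$F0), 0)
  eA <- al$elements$Al$shells$K$transitions[[1]]$e
  gj <- bfpdose:::.group_of(gs, eA)
  expect_true(all(rel$F0[, setdiff(1:30, gj)] == 0))
  ## production feeds only the l = 0 moment of the assembled library
  lib <- assemble_library(al, gs, L = 3, channels = "relaxation")
  for (l in 1:3) expect_true(all(lib$mat$aluminium$S[l + 1, , ] == 0))
  ## and is excluded from the total reaction rate
  expect_true(all(lib$mat$aluminium$Sig_t == 0))
})

test_that("subshell ionization estimate matches its quadrature oracle", {
  E <- 0.5; U <- 1.56e-3
  or <- stats::integrate(function(w) moller_dcs(E, w), U, E / 2,
                         rel.tol = 1e-10)$value * 2
  expect_equal(bfpdose:::.shell_ion_xs(E, U, 2), or, tolerance = 1e-7)
})

test_that("energy deposition collapses to the restricted stopping power
           when catastrophic channels are off", {
  gs <- make_groups(1.0, 12)
  lib <- assemble_library("water", gs, L = 2, channels = character(0))
  m <- lib$mat$water
  expect_equal(m$E_dep, m$beta_c + m$beta_b, tolerance = 1e-12)
  ## full physics: Auger charge deposition is a removal (negative)
  full <- fix_lib_small()
  al_gs <- make_groups(1.0, 12)
  al_lib <- assemble_library("aluminium", al_gs, L = 2)
  rel <- relaxation_feed(nist_material("aluminium"), al_gs)
  expect_true(all(-rowSums(rel$F0) <= 0))
})

test_that("catastrophic energy bookkeeping tightens under group refinement", {
  w <- fix_water()
  err_at <- function(N) {
    gs <- make_groups(1.0, N)
    ion <- ionization_feed(w, gs, L = 0)
    f1 <- rowSums(ion$F1_ee[1, , ]) + rowSums(ion$F1_ed[1, , ])
    nz <- ion$T > 0
    ## free-electron collisions conserve energy exactly at fixed E; the
    ## residual is the flat-flux group-averaging mismatch
    max(abs(f1[nz] - gs$Eavg[nz] * ion$T[nz]) / (gs$Eavg[nz] * ion$T[nz]))
  }
  e30 <- err_at(30); e60 <- err_at(60)
  expect_lt(e60, e30)
  expect_lt(e60, 0.02)
})

test_that("library round trip through the text container is exact", {
  lib <- fix_lib_small()
  f <- tempfile(fileext = ".json")
  write_library(lib, f)
  lib2 <- read_library(f)
  expect_equal(lib2$groups$boundaries, lib$groups$boundaries,
               tolerance = 0)
  for (fld in c("Sig_t", "S", "beta_c", "beta_b", "beta_lo", "E_dep",
                "alpha", "R", "elastic_F_corr")) {
    expect_equal(lib2$mat$water[[fld]], lib$mat$water[[fld]],
                 tolerance = 0, ignore_attr = TRUE)
  }
  expect_equal(lib2$mat$water$material$electron_density,
               lib$mat$water$material$electron_density)
  ## corruption is caught by the checksum, alien files by the magic line
  txt <- readLines(f)
  txt[2] <- sub("\\[", "[9999.0,", txt[2])
  f2 <- tempfile(); writeLines(txt, f2)
  expect_error(read_library(f2), "checksum")
  f3 <- tempfile(); writeLines(c("not a library", "{}"), f3)
  expect_error(read_library(f3), "not a bfpdose")
})

test_that("the total catastrophic cross section is the sum of its
           channels", {
  lib <- fix_lib_small()
  m <- lib$mat$water
  expect_lt(max(abs(m$Sig_t - (m$T_c + m$T_b + m$T_e_corr))), 1e-10)
  ## no up-scatter: with group 1 the highest energy, sinks never have a
  ## smaller index than their source (S0[g, g'] = 0 for g' < g)
  S0 <- m$S[1, , ]
  expect_true(all(S0[lower.tri(S0)] == 0))
})
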