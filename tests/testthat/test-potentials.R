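db <- default_material_db()

test_that("Hamaker constants vanish for matched media and are symmetric", {
  w2 <- hamaker_material("w2", "dielectric", 78.4, 1.333, 3.0e15)
  expect_equal(hamaker_constant(w2, db$polystyrene, db$water)$A_J, 0)
  expect_equal(hamaker_constant(db$polystyrene, w2, db$water)$A_J, 0)
  a12 <- hamaker_constant(db$polystyrene, db$lipid, db$water)$A_J
  a21 <- hamaker_constant(db$lipid, db$polystyrene, db$water)$A_J
  expect_equal(a12, a21)
  expect_error(hamaker_constant(db$water, db$water, db$silver), "conducting")
})

test_that("dielectric pair matches the independently coded two-term closed form", {
  # oracle: textbook zero-frequency + dispersion terms, coded from scratch
  oracle <- function(e1, e2, n1, n2, nu, e3 = 78.4, n3 = 1.333, T = 298) {
    kT <- 1.380649e-23 * T
    h <- 6.62607015e-34
    s1 <- n1^2 + n3^2; s2 <- n2^2 + n3^2
    0.75 * kT * ((e1 - e3) / (e1 + e3)) * ((e2 - e3) / (e2 + e3)) +
      (3 * h * nu / (8 * sqrt(2))) * (n1^2 - n3^2) * (n2^2 - n3^2) /
        (sqrt(s1) * sqrt(s2) * (sqrt(s1) + sqrt(s2)))
  }
  got <- hamaker_constant(db$polystyrene, db$polystyrene, db$water, 298)
  expect_equal(got$A_J, oracle(2.55, 2.55, 1.557, 1.557, 3.0e15),
               tolerance = 1e-10)
  # textbook ballpark for polystyrene across water: ~1.3e-20 J
  expect_gt(got$A_J, 1.0e-20)
  expect_lt(got$A_J, 1.7e-20)
  # unlike pair with nu_e mixing sqrt(nu1 nu3)
  lip <- db$lipid; lip$frequency <- 2.5e15
  got2 <- hamaker_constant(db$polystyrene, lip, db$water, 298)
  mix <- function(nu) sqrt(nu * 3.0e15)
  kTT <- 1.380649e-23 * 298; hh <- 6.62607015e-34
  s1 <- 1.557^2 + 1.333^2; s2 <- 1.44^2 + 1.333^2
  w1 <- mix(3.0e15) * sqrt(s1 / 2); w2 <- mix(2.5e15) * sqrt(s2 / 2)
  a1 <- (1.557^2 - 1.333^2) / s1; a2 <- (1.44^2 - 1.333^2) / s2
  want <- 0.75 * kTT * ((2.55 - 78.4) / (2.55 + 78.4)) *
    ((2.0 - 78.4) / (2.0 + 78.4)) +
    (3 * hh / 8) * a1 * a2 * w1 * w2 / (w1 + w2)
  expect_equal(got2$A_J, want, tolerance = 1e-12)
})

test_that("like materials across any solvent attract (A_131 >= 0)", {
  withr::with_seed(7, {
    for (k in 1:25) {
      m <- hamaker_material("m", "dielectric", stats::runif(1, 1.5, 90),
                            stats::runif(1, 1.0, 1.8),
                            stats::runif(1, 1e15, 5e15))
      s <- hamaker_material("s", "dielectric", stats::runif(1, 1.5, 90),
                            stats::runif(1, 1.0, 1.8),
                            stats::runif(1, 1e15, 5e15))
      expect_gte(hamaker_constant(m, m, s)$A_J, 0)
    }
  })
})

test_that("conducting particles use the plasma-frequency variant", {
  a_metal <- hamaker_constant(db$amino_acid, db$silver, db$water, 300)
  expect_gt(a_metal$A_J, 1e-20) # metals bind strongly across water
  # zero-frequency reflection of a conductor is total
  expect_equal(a_metal$static_J,
               0.75 * 1.380649e-23 * 300 * (4.0 - 78.4) / (4.0 + 78.4),
               tolerance = 1e-12)
})

test_that("core potential reproduces the sphere-half-space closed form", {
  # A = 1e-20 J, R = 10 nm, gap 1 nm at 298 K: about -3.0 kT
  u <- core_potential(1e-20, "slab", bead_radius = 10, h = 1,
                      temperature = 298)
  want <- -(1e-20 / 6) * (10 / 1 + 10 / 21 + log(1 / 21)) /
    (1.380649e-23 * 298)
  expect_equal(u, want, tolerance = 1e-12)
  expect_equal(u, -3.01, tolerance = 1e-3)
  expect_equal(core_potential(0, "slab", bead_radius = 0.3, h = 0.5), 0)
  expect_error(core_potential(1e-20, "slab", bead_radius = 0.3, h = 0),
               "h > 0")
  # linear in A, attractive, decaying
  hs <- seq(0.2, 5, by = 0.1)
  u1 <- core_potential(1e-20, "slab", 0.3, hs)
  u2 <- core_potential(2e-20, "slab", 0.3, hs)
  expect_equal(u2, 2 * u1, tolerance = 1e-12)
  expect_true(all(u1 < 0))
  expect_true(all(diff(u1) > 0)) # monotone toward zero
})

test_that("the two-sphere form approaches the half-space form for huge particles", {
  hs <- seq(0.2, 2, by = 0.2)
  u_sph <- core_potential(1e-20, "sphere", bead_radius = 0.3, h = hs,
                          np_radius = 1e4)
  u_slab <- core_potential(1e-20, "slab", bead_radius = 0.3, h = hs)
  expect_equal(u_sph, u_slab, tolerance = 0.01)
})

test_that("core correction removes exactly the parametrization-slab dispersion", {
  expect_equal(core_correction(0, "slab", 0.3, h = 0.4), 0)
  # degenerate slab: correction equals the full core potential
  u0 <- core_correction(1e-20, "slab", 0.3, h = 0.4, slab_thickness = 0)
  expect_equal(u0, core_potential(1e-20, "slab", 0.3, h = 0.4),
               tolerance = 1e-10)
  us <- core_correction(1e-20, "sphere", 0.3, h = 0.4, np_radius = 10,
                        slab_thickness = 0)
  expect_equal(us, core_potential(1e-20, "sphere", 0.3, h = 0.4,
                                  np_radius = 10), tolerance = 1e-10)

  # flat geometry, finite slab: oracle integrates the sheet-energy density
  # of the half-space form over the missing depth range [gap+t, infinity)
  A <- 1.3e-20; R <- 0.3; gap <- 0.35; t <- 1.1
  u_hs <- function(s) -(A / 6) * (R / s + R / (s + 2 * R) + log(s / (s + 2 * R)))
  dens <- function(x) {
    eps <- 1e-6
    -(u_hs(x + eps) - u_hs(x - eps)) / (2 * eps) # -dU/ds sheet density
  }
  want_J <- stats::integrate(function(x) dens(x), gap + t, 200,
                             rel.tol = 1e-9)$value + u_hs(200)
  got <- core_correction(A, "slab", R, h = gap, slab_thickness = t)
  expect_lt(abs(got - want_J / (1.380649e-23 * 300)), 1e-4)
  expect_error(core_correction(1e-20, "slab", 0.3, h = 0.9, r_c = 1.0),
               "r_c")
})

test_that("tabulated profiles interpolate through nodes and obey the cutoff", {
  h <- seq(0.1, 1.0, by = 0.02)
  quad <- 4 * (h - 0.5)^2 - 1.2 # analytic quadratic, zero-crossing inside
  tab <- pmf_table(h, quad - (4 * (0.95 - 0.5)^2 - 1.2), r_c = 1.0,
                   zero_ref = FALSE)
  # nodes strictly inside the cutoff are reproduced exactly
  inside <- h < 1.0
  expect_equal(surface_pmf_eval(tab, h[inside]), tab$data$energy[inside],
               tolerance = 1e-12)
  # beyond the cutoff: exactly zero
  expect_identical(surface_pmf_eval(tab, c(1.0, 1.5, 7)), c(0, 0, 0))
  # midpoints of a quadratic recovered by the monotone cubic interpolant
  mids <- h[5:20] + 0.01
  want <- (4 * (mids - 0.5)^2 - 1.2) - (4 * (0.95 - 0.5)^2 - 1.2)
  expect_equal(surface_pmf_eval(tab, mids), want, tolerance = 1e-3)
})

test_that("sub-grid extrapolation is a capped repulsive wall", {
  tab <- synth_pmf(synthetic_pmf_spec())
  h_min <- tab$data$h[1]
  just_below <- surface_pmf_eval(tab, h_min - 0.01)
  expect_gt(just_below, surface_pmf_eval(tab, h_min))
  expect_equal(surface_pmf_eval(tab, -0.5), 50)
  expect_lte(surface_pmf_eval(tab, 0.0001), 50)
})

test_that("electrostatic term follows the screened surface-potential decay", {
  med <- medium(saline_species(0.15), 78.4, 298.15)
  slab <- nanoparticle("slab", zeta_mV = -25.69, facets = "110")
  expect_equal(electrostatic_energy(0, slab, med, c(0, 1, 2)), c(0, 0, 0))
  neutral <- nanoparticle("slab", zeta_mV = 0, facets = "110")
  expect_equal(electrostatic_energy(1, neutral, med, c(0, 1)), c(0, 0))
  # e * 25.69 mV equals kT at 298.15 K
  expect_equal(electrostatic_energy(1, slab, med, 0), -1.0, tolerance = 1e-3)
  # strict monotone decay toward zero for kappa > 0
  hs <- seq(0, 5, by = 0.1)
  u <- electrostatic_energy(1, slab, med, hs)
  expect_true(all(diff(u) > 0) && all(u < 0))
  sph <- nanoparticle("sphere", radius = 10, zeta_mV = 25.69, facets = "110")
  us <- electrostatic_energy(1, sph, med, hs)
  expect_true(all(diff(us) < 0) && all(us > 0))
  # curvature factor R/(R+h)
  expect_equal(us[1] / electrostatic_energy(1, slab, med, 0), -1,
               tolerance = 1e-9)
  expect_equal(us[11] / abs(electrostatic_energy(1, slab, med, 1)),
               10 / 11, tolerance = 1e-9)
})

test_that("bead energy assembles the three published terms", {
  med <- medium()
  np <- nanoparticle("slab", zeta_mV = -20, facets = "110")
  bead <- registry_lookup(default_bead_registry(), "LYS")
  tab <- synth_pmf(synthetic_pmf_spec(bead = "LYS"))
  A <- hamaker_constant(db$amino_acid, db$silver, db$water, 300)

  # all terms zero -> zero everywhere
  zb <- registry_lookup(default_bead_registry(), "ALA")
  zt <- zero_pmf()
  hs <- c(0.1, 0.5, 0.9, 1.5, 3)
  np0 <- nanoparticle("slab", zeta_mV = 0, facets = "110")
  expect_equal(bead_energy(zb, zt, 0, np0, med, hs), rep(0, 5))

  # term-by-term oracle inside and outside the cutoff
  h_in <- c(0.3, 0.6, 0.85)
  gap <- pmin(pmax(h_in - bead$radius, 0.01), tab$r_c - bead$radius - 1e-9)
  want_in <- surface_pmf_eval(tab, h_in) +
    core_correction(A, "slab", bead$radius, gap, slab_thickness = 1.1,
                    r_c = tab$r_c) +
    electrostatic_energy(bead$charge, np, med, h_in)
  expect_equal(bead_energy(bead, tab, A, np, med, h_in), want_in,
               tolerance = 1e-12)
  h_out <- c(1.0, 1.4, 2.5)
  want_out <- core_potential(A, "slab", bead$radius,
                             pmax(h_out - bead$radius, 0.01)) +
    electrostatic_energy(bead$charge, np, med, h_out)
  expect_equal(bead_energy(bead, tab, A, np, med, h_out), want_out,
               tolerance = 1e-12)

  # missing table for the particle facet is an informative error
  np111 <- nanoparticle("slab", zeta_mV = 0, facets = "111")
  expect_error(bead_energy(bead, tab, A, np111, med, 0.5), "facet")
})

test_that("nonbonded branches are continuous at the cutoff", {
  med <- medium()
  np <- nanoparticle("slab", zeta_mV = -20, facets = "110")
  A <- hamaker_constant(db$amino_acid, db$silver, db$water, 300)
  specs <- list(
    synthetic_pmf_spec(bead = "ALA"),
    synthetic_pmf_spec(depths = c(-8, -1), bead = "ARG", noise = 0.4,
                       seed = 4),
    synthetic_pmf_spec(depths = -2, locations = 0.3, widths = 0.06,
                       bead = "SER", r_c = 1.2)
  )
  for (sp in specs) {
    tab <- synth_pmf(sp)
    bead <- registry_lookup(default_bead_registry(), sp$bead)
    lo <- bead_energy(bead, tab, A, np, med, tab$r_c - 1e-6)
    hi <- bead_energy(bead, tab, A, np, med, tab$r_c + 1e-6)
    expect_lt(abs(lo - hi), 0.25)
  }
})
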