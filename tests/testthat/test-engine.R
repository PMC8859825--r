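med <- medium()
slab0 <- nanoparticle("slab", zeta_mV = 0, facets = "110")

test_that("configuration energy is the pairwise-additive per-bead sum", {
  lib <- well_lib(list(ALA = -3, LYS = -6, ASP = -1.5))
  np <- nanoparticle("slab", zeta_mV = -15, facets = "110")
  # single bead: equals bead_energy at that bead's SSD
  one <- toy_protein(1, "line", "LYS")$protein
  st <- configuration_state(0, 0, z = 0.31)
  A <- hamaker_constant(default_material_db()$amino_acid,
                        default_material_db()$silver,
                        default_material_db()$water, med$temperature)
  got <- configuration_energy(one, np, med, lib, st)
  bead <- registry_lookup(default_bead_registry(), "LYS")
  expect_equal(got, bead_energy(bead, pmf_lookup(lib, "LYS", "110"), A, np,
                                med, 0.31), tolerance = 1e-10)

  # all-zero potentials: zero for every state
  zlib <- pmf_library(list(zero_pmf("ALA"), zero_pmf("LYS"),
                           zero_pmf("ASP")))
  coil <- toy_protein(5, "random-coil", c("ALA", "LYS", "ASP"),
                      seed = 2)$protein
  for (z in c(0.8, 1.5, 4)) {
    expect_equal(configuration_energy(coil, slab0, med, zlib,
                                      configuration_state(0.4, 1.1, z),
                                      hamaker = list(amino_acid = 0)), 0)
  }

  # 5-bead fixture vs an independently coded per-bead loop
  st2 <- configuration_state(0.7, 2.3, 1.4)
  got2 <- configuration_energy(coil, np, med, lib, st2)
  rot_xyz <- oracle_rotate(bead_coords(coil), coil$com, st2$theta, st2$phi)
  want2 <- 0
  for (i in seq_len(5)) {
    b <- coil$beads[i, ]
    h_i <- st2$z + (rot_xyz[i, 3] - coil$com[3])
    want2 <- want2 + bead_energy(b, pmf_lookup(lib, b$pmf_name, "110"), A,
                                 np, med, h_i)
  }
  expect_equal(got2, unname(want2), tolerance = 1e-9)
})

test_that("mean energy over z matches closed forms and a quadrature oracle", {
  # zero field
  expect_equal(mean_energy_over_z(function(z) 0 * z, 0, 2, "slab")$E, 0)
  # square well, slab measure: closed form of the piecewise profile
  sq <- function(z) ifelse(z >= 0.2 & z < 0.4, -5, 0)
  got <- mean_energy_over_z(sq, 0, 2, "slab")
  expect_equal(got$E, (0.2 * (-5) * exp(5)) / (0.2 * exp(5) + 1.8),
               tolerance = 1e-6)
  expect_equal(got$a, 2)
  # sphere measure vs an independent fine fixed-grid quadrature
  U <- function(z) -4 * exp(-(z - 10.4)^2 / 0.02) + 0.8 * exp(-(z - 10.2)^2 / 0.01)
  got_s <- mean_energy_over_z(U, 10, 12, "sphere")$E
  zz <- seq(10, 12, by = 1e-4)
  w <- exp(-U(zz)) * zz^2
  want_s <- sum(U(zz) * w) / sum(w)
  expect_lt(abs(got_s - want_s), 1e-3)
  # non-decaying profile is rejected
  expect_error(mean_energy_over_z(function(z) -3 + 0 * z, 0, 2, "slab"),
               "decay")
})

test_that("orientation map is zero for zero potentials and symmetric for a point", {
  zlib <- pmf_library(list(zero_pmf("ALA")))
  one <- toy_protein(1, "line", "ALA")$protein
  m0 <- orientation_map(one, slab0, med, zlib, grid = orientation_grid(45),
                        hamaker = list(amino_acid = 0))
  expect_true(all(m0$E == 0))
  expect_equal(average_simple(m0), 0)
  expect_equal(average_boltzmann(m0)$E_ads_B, 0)

  # a single bead has no orientation dependence
  lib <- well_lib(list(ALA = -4))
  m1 <- orientation_map(one, slab0, med, zlib <- lib,
                        grid = orientation_grid(45),
                        hamaker = list(amino_acid = 0))
  expect_lt(diff(range(m1$E)), 1e-9)
})

test_that("the argmin orientation points the binding bead at the surface", {
  lib <- well_lib(list(LYS = -8, ALA = 2)) # one binder, one repelled bead
  rod <- toy_protein(2, "dumbbell", c("ALA", "LYS"))$protein # LYS at +z
  m <- orientation_map(rod, slab0, med, lib, grid = orientation_grid(30),
                       hamaker = list(amino_acid = 0))
  best <- m[which.min(m$U_min), ]
  # brute-force oracle over the same coarse grid: minimum must sit where the
  # LYS bead is closest to the surface (theta near pi flips +z down)
  expect_gt(best$theta, pi / 2)
  pose <- lowest_energy_pose(m, rod, slab0, med, lib,
                             hamaker = list(amino_acid = 0))
  expect_equal(pose$contacts$bead, "LYS")
  expect_equal(nrow(pose$contacts), 1)
})

test_that("orientation averages obey their closed forms and inequality", {
  # constant map
  cmap <- tibble::tibble(weight = rep(0.25, 4), E = rep(-2.5, 4))
  expect_equal(average_simple(cmap), -2.5)
  bz <- average_boltzmann(cmap)
  expect_equal(bz$E_ads_B, -2.5)
  expect_equal(bz$P, rep(0.25, 4))
  # two equal-weight orientations {0, -10}
  two <- tibble::tibble(weight = c(0.5, 0.5), E = c(0, -10))
  expect_equal(average_simple(two), -5)
  expect_equal(average_boltzmann(two)$E_ads_B, -10 * exp(10) / (1 + exp(10)),
               tolerance = 1e-9)
  # random maps: weighted-mean oracle and E_B <= E_A
  for (s in 1:100) {
    m <- random_map(seed = s)
    expect_equal(average_simple(m), sum(m$weight * m$E) / sum(m$weight),
                 tolerance = 1e-12)
    expect_lte(average_boltzmann(m)$E_ads_B, average_simple(m) + 1e-12)
  }
})

test_that("facet averaging is a weighted arithmetic mean with guards", {
  expect_equal(facet_average(c(`100` = -30, `110` = -60, `111` = -90)), -60)
  expect_equal(facet_average(c(`110` = -42)), -42)
  expect_equal(facet_average(c(`100` = -30, `110` = -60, `111` = -90),
                             c(`100` = 1, `110` = 0, `111` = 0)), -30)
  expect_error(facet_average(c(`100` = -30),
                             c(`100` = 0.5, `110` = 0.5)), "110")
})

test_that("single-bead adsorption on a slab recovers the 1-D Boltzmann integral", {
  tab <- synth_pmf(synthetic_pmf_spec(depths = -5, locations = 0.25,
                                      widths = 0.05, bead = "ALA"))
  lib <- pmf_library(list(tab))
  one <- toy_protein(1, "line", "ALA")$protein
  m <- orientation_map(one, slab0, med, lib, grid = orientation_grid(45),
                       hamaker = list(amino_acid = 0))
  z_lo <- tab$data$h[1]
  zz <- seq(z_lo, z_lo + m$a[1], by = 1e-4)
  u <- surface_pmf_eval(tab, zz)
  w <- exp(-u)
  want <- sum(u * w) / sum(w)
  expect_lt(abs(average_simple(m) - want), 1e-3)
  expect_lt(abs(average_boltzmann(m)$E_ads_B - want), 1e-3)
})

test_that("engine energies match a brute-force nested-loop reference", {
  lib <- well_lib(list(ALA = -3, LYS = -6, ASP = -1.5))
  np <- nanoparticle("sphere", radius = 5, zeta_mV = -15, facets = "110")
  coil <- toy_protein(3, "random-coil", c("ALA", "LYS", "ASP"),
                      seed = 9)$protein
  grid <- orientation_grid(60)
  m <- orientation_map(coil, np, med, lib, grid = grid)
  db <- default_material_db()
  A <- hamaker_constant(db$amino_acid, db$silver, db$water, med$temperature)
  h_contact <- max(purrr::map_dbl(lib, ~ .x$data$h[1]))
  for (k in seq_len(nrow(grid))) {
    rot_xyz <- oracle_rotate(bead_coords(coil), coil$com,
                             grid$theta[k], grid$phi[k])
    pos <- sweep(rot_xyz, 2, coil$com)
    # contact separation: closest bead at h_contact
    f <- function(z) min(sqrt(pos[, 1]^2 + pos[, 2]^2 + (pos[, 3] + z)^2)) -
      np$radius - h_contact
    z_lo <- stats::uniroot(f, c(1e-3, np$radius + 5), tol = 1e-9)$root
    z_hi <- z_lo + m$a[k]
    zz <- seq(z_lo, z_hi, length.out = 4001)
    utot <- numeric(length(zz))
    for (i in 1:3) {
      b <- coil$beads[i, ]
      h_i <- sqrt(pos[i, 1]^2 + pos[i, 2]^2 + (pos[i, 3] + zz)^2) - np$radius
      utot <- utot + bead_energy(b, pmf_lookup(lib, b$pmf_name, "110"), A,
                                 np, med, h_i)
    }
    w <- exp(-(utot - min(utot))) * zz^2
    want <- sum(utot * w) / sum(w)
    expect_lt(abs(m$E[k] - want), 1e-3)
  }
})

test_that("halving the orientation grid changes the Boltzmann average by < 2%", {
  # fixture with an orientation map that a 30-degree grid can resolve
  lib <- well_lib(list(LYS = -5, ALA = -2), location = 0.3, width = 0.12)
  rod <- toy_protein(2, "dumbbell", c("ALA", "LYS"), spacing = 0.4)$protein
  m_coarse <- orientation_map(rod, slab0, med, lib,
                              grid = orientation_grid(30),
                              hamaker = list(amino_acid = 0))
  m_fine <- orientation_map(rod, slab0, med, lib,
                            grid = orientation_grid(15),
                            hamaker = list(amino_acid = 0))
  eb1 <- average_boltzmann(m_coarse)$E_ads_B
  eb2 <- average_boltzmann(m_fine)$E_ads_B
  expect_lt(abs(eb1 - eb2) / abs(eb2), 0.02)
})

test_that("pose extraction is deterministic and byte-stable", {
  lib <- well_lib(list(LYS = -8, ALA = 2))
  rod <- toy_protein(2, "dumbbell", c("ALA", "LYS"))$protein
  m <- orientation_map(rod, slab0, med, lib, grid = orientation_grid(45),
                       hamaker = list(amino_acid = 0))
  f1 <- withr::local_tempfile(fileext = ".pdb")
  f2 <- withr::local_tempfile(fileext = ".pdb")
  p1 <- lowest_energy_pose(m, rod, slab0, med, lib,
                           hamaker = list(amino_acid = 0), pdb_path = f1)
  p2 <- lowest_energy_pose(m, rod, slab0, med, lib,
                           hamaker = list(amino_acid = 0), pdb_path = f2)
  expect_identical(readLines(f1), readLines(f2))
  expect_equal(p1$state$z, p2$state$z)
  # single-bead protein: that bead is the sole contact
  one <- toy_protein(1, "line", "LYS")$protein
  m1 <- orientation_map(one, slab0, med, lib, grid = orientation_grid(90),
                        hamaker = list(amino_acid = 0))
  pose1 <- lowest_energy_pose(m1, one, slab0, med, lib,
                              hamaker = list(amino_acid = 0))
  expect_equal(nrow(pose1$contacts), 1)
})

test_that("full adsorption run averages facets and reports both units", {
  libs <- pmf_library(c(
    well_lib(list(LYS = -6, ALA = -2), facet = "110"),
    well_lib(list(LYS = -4, ALA = -1), facet = "111")
  ))
  np <- nanoparticle("sphere", radius = 8, zeta_mV = -10,
                     facets = c("110", "111"))
  rod <- toy_protein(2, "dumbbell", c("ALA", "LYS"))$protein
  fit <- adsorb_protein(rod, np, med, libs, grid = orientation_grid(45))
  expect_s3_class(fit, "ns_adsorption")
  expect_equal(fit$E_ads_A, mean(fit$per_facet$E_ads_A))
  expect_equal(fit$E_ads_B, mean(fit$per_facet$E_ads_B))
  expect_equal(fit$E_ads_B_kJmol, fit$E_ads_B * kT_kjmol(med$temperature))
  expect_lte(fit$E_ads_B, fit$E_ads_A)
  g <- glance(fit)
  expect_equal(nrow(g), 1)
  expect_equal(g$E_ads_B, fit$E_ads_B)
  t <- tidy(fit)
  expect_equal(nrow(t), 2)
  expect_s3_class(autoplot(fit$maps[["110"]]), "ggplot")
})
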