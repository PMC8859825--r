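#' Orientation grid over the sphere
#'
#' Protein orientations are sampled on a regular (theta, phi) grid with
#' solid-angle weights proportional to sin(theta), normalized to sum to 1, so
#' orientation averages are unbiased over the sphere.
#'
#' @param step_deg Grid spacing in degrees (default 5).
#' @return An object of class `ns_grid`: a tibble with columns `theta`, `phi`
#'   (radians) and `weight`.
#' @export
orientation_grid <- function(step_deg = 5) {
  stopifnot(step_deg > 0, step_deg <= 90)
  step <- step_deg * pi / 180
  theta <- seq(0, pi, by = step)
  phi <- seq(0, 2 * pi - step / 2, by = step)
  g <- tidyr::expand_grid(theta = theta, phi = phi)
  w <- sin(g$theta)
  g$weight <- w / sum(w)
  structure(g, class = c("ns_grid", class(g)), step_deg = step_deg)
}

#' Boltzmann-weighted mean energy over a separation interval
#'
#' Averages an interaction-energy profile U(z) over the separation interval
#' `[z_lo, z_hi]` with Boltzmann weight exp(-U/kT) and the geometric measure
#' of the configuration volume: dz for a flat slab, z^2 dz for a spherical
#' particle (volume element about the particle centre). Quadrature is adaptive
#' with relative tolerance 1e-4; exponential overflow is guarded by shifting
#' by the profile minimum.
#'
#' @param U A vectorized function of z (nm) returning energy in kT.
#' @param z_lo,z_hi Interval bounds in nm.
#' @param geometry `"slab"` or `"sphere"`.
#' @param decay_tol The profile must have decayed to |U| below this at `z_hi`
#'   (default 0.05 kT), otherwise the interval is too short and an error is
#'   raised.
#' @return A one-row tibble with `E` (kT) and `a` (interval length, nm).
#' @examples
#' sq <- function(z) ifelse(z >= 0.2 & z < 0.4, -5, 0)
#' mean_energy_over_z(sq, 0, 2, "slab")   # approx -4.71 kT
#' @export
mean_energy_over_z <- function(U, z_lo, z_hi, geometry = c("slab", "sphere"),
                               decay_tol = 0.05) {
  geometry <- match.arg(geometry)
  stopifnot(z_hi > z_lo)
  if (abs(U(z_hi)) > decay_tol) {
    stop("profile has not decayed at z_far (|U| = ", signif(abs(U(z_hi)), 3),
         " kT): interval too short")
  }
  zs <- seq(z_lo, z_hi, length.out = 257)
  u0 <- min(U(zs))
  w <- if (geometry == "sphere") function(z) z^2 else function(z) 1 + 0 * z
  denom <- stats::integrate(function(z) exp(-(U(z) - u0)) * w(z),
                            z_lo, z_hi, rel.tol = 1e-4,
                            subdivisions = 500L)$value
  numer <- stats::integrate(function(z) U(z) * exp(-(U(z) - u0)) * w(z),
                            z_lo, z_hi, rel.tol = 1e-4,
                            subdivisions = 500L, stop.on.error = FALSE)$value
  tibble::tibble(E = numer / denom, a = z_hi - z_lo)
}

# Per-bead SSD for a rotated protein with COM at separation z from the
# particle (vectorized over z). `pos` are bead offsets from the COM.
.bead_ssd <- function(pos, z, np) {
  if (np$shape == "sphere") {
    rho2 <- matrix(pos[, 1]^2 + pos[, 2]^2, nrow = length(z),
                   ncol = nrow(pos), byrow = TRUE)
    sqrt(rho2 + outer(z, pos[, 3], `+`)^2) - np$radius
  } else {
    outer(z, pos[, 3], `+`)
  }
}

# Vectorized total energy profile U(z) for one orientation. Returns a
# function of z built over the rotated bead offsets.
.profile_fun <- function(rot, np, med, tables, facet, hamaker,
                         slab_thickness) {
  b <- rot$beads
  pos <- sweep(as.matrix(b[, c("x", "y", "z")]), 2, rot$com)
  tab_list <- lapply(b$pmf_name, function(nm) pmf_lookup(tables, nm, facet))
  mat_ids <- .ensure_material(b)$material_id
  function(z) {
    hmat <- .bead_ssd(pos, z, np) # length(z) x n_beads
    hmat <- pmax(hmat, 1e-6)
    tot <- numeric(length(z))
    for (i in seq_len(nrow(b))) {
      tot <- tot + bead_energy(b[i, ], tab_list[[i]], hamaker[[mat_ids[i]]],
                               np, med, hmat[, i],
                               slab_thickness = slab_thickness)
    }
    tot
  }
}

#' Map of per-orientation mean adsorption energies
#'
#' For every orientation node (theta_k, phi_l) the protein is rigidly rotated,
#' the total interaction energy is scanned along the separation z from first
#' steric contact out to where the interaction has decayed, and the
#' Boltzmann-weighted mean energy over that interval is recorded together with
#' the interval length a(theta_k, phi_l). Deterministic for fixed inputs.
#'
#' @inheritParams configuration_energy
#' @param grid An [orientation_grid()].
#' @param h_contact SSD (nm) defining first steric contact of the closest
#'   bead; defaults to the first grid point of the tables.
#' @param decay_kT Scan outward until the total |U| falls below this (kT).
#' @return An `ns_adsorption_map`: a tibble with columns `theta`, `phi`,
#'   `weight`, `E` (kT), `a` (nm), `U_min` (kT), `z_min` (nm), with the facet
#'   and particle attached as attributes.
#' @export
orientation_map <- function(protein, np, med, tables,
                            grid = orientation_grid(5),
                            facet = np$facets[1],
                            h_contact = NULL, decay_kT = 1e-3,
                            hamaker = NULL,
                            materials = default_material_db(),
                            solvent_id = "water",
                            slab_thickness = 1.1) {
  stopifnot(inherits(protein, "ns_protein"), inherits(np, "ns_nanoparticle"))
  protein$beads <- b <- .ensure_material(protein$beads)
  if (is.null(hamaker)) {
    hamaker <- .hamaker_map(protein, np, med, materials, solvent_id)
  }
  if (is.null(h_contact)) {
    h_contact <- max(purrr::map_dbl(unique(b$pmf_name), function(nm) {
      pmf_lookup(tables, nm, facet)$data$h[1]
    }))
  }
  rows <- purrr::pmap_dfr(grid[, c("theta", "phi")], function(theta, phi) {
    rot <- rotate_protein(protein, theta, phi)
    pos <- sweep(as.matrix(rot$beads[, c("x", "y", "z")]), 2, rot$com)
    Uf <- .profile_fun(rot, np, med, tables, facet, hamaker, slab_thickness)
    z_lo <- .contact_separation(pos, np, h_contact)
    z_hi <- .decay_separation(Uf, z_lo, decay_kT)
    # coarse scan locates the energy minimum along z for the pose search
    zs <- seq(z_lo, z_hi, by = 0.01)
    us <- Uf(zs)
    i0 <- which.min(us)
    opt <- stats::optimize(Uf, c(max(z_lo, zs[i0] - 0.01),
                                 min(z_hi, zs[i0] + 0.01)))
    me <- mean_energy_over_z(Uf, z_lo, z_hi,
                             geometry = if (np$shape == "sphere") "sphere"
                                        else "slab")
    tibble::tibble(theta = theta, phi = phi, E = me$E, a = me$a,
                   U_min = min(opt$objective, us[i0]),
                   z_min = if (opt$objective <= us[i0]) opt$minimum else zs[i0])
  })
  out <- dplyr::bind_cols(rows[, c("theta", "phi")],
                          weight = grid$weight,
                          rows[, c("E", "a", "U_min", "z_min")])
  if (!all(is.finite(out$E))) stop("non-finite orientation energies")
  structure(out,
            class = c("ns_adsorption_map", class(tibble::tibble())),
            facet = facet, np = np, protein_id = protein$source_id,
            temperature = med$temperature)
}

# smallest separation at which the closest bead sits at h_contact
.contact_separation <- function(pos, np, h_contact) {
  if (np$shape == "slab") {
    h_contact - min(pos[, 3])
  } else {
    f <- function(z) min(sqrt(pos[, 1]^2 + pos[, 2]^2 + (pos[, 3] + z)^2)) -
      np$radius - h_contact
    hi <- np$radius + h_contact + max(sqrt(rowSums(pos^2))) + 0.1
    lo <- max(1e-3, np$radius + h_contact - max(sqrt(rowSums(pos^2))) - 0.1)
    while (f(lo) > 0 && lo > 1e-3) lo <- lo / 2
    stats::uniroot(f, c(lo, hi), tol = 1e-6)$root
  }
}

# extend the interval outward until the interaction has decayed
.decay_separation <- function(Uf, z_lo, decay_kT) {
  z <- z_lo + 1.5
  while (abs(Uf(z)) > decay_kT && z < z_lo + 40) z <- z + 0.5
  z + 0.5
}

#' Simple (arithmetic) orientation average
#'
#' Solid-angle-weighted arithmetic mean of the per-orientation mean energies:
#' the simple-average adsorption energy E_ads^A.
#'
#' @param map An `ns_adsorption_map` (or any data frame with `E` and `weight`
#'   columns).
#' @return E_ads^A in kT (scalar).
#' @export
average_simple <- function(map) {
  stopifnot(all(c("E", "weight") %in% names(map)))
  sum(map$weight * map$E) / sum(map$weight)
}

#' Boltzmann (canonical) orientation average
#'
#' Canonical average with Boltzmann weighting factors
#' `P_kl` proportional to `w_kl exp(-E_kl/kT)`, yielding the ensemble-average
#' adsorption energy E_ads^B. Always `E_ads^B <= E_ads^A`. Overflow is guarded
#' by shifting energies by their minimum before exponentiation.
#'
#' @param map An `ns_adsorption_map`.
#' @param weighted Include the solid-angle weights in P (default TRUE); set
#'   FALSE for plain Boltzmann weights over the raw grid.
#' @return A list with `E_ads_B` (kT) and `P` (normalized weights, one per
#'   orientation row).
#' @export
average_boltzmann <- function(map, weighted = TRUE) {
  stopifnot(all(c("E", "weight") %in% names(map)))
  w <- if (weighted) map$weight else rep(1, nrow(map))
  p <- w * exp(-(map$E - min(map$E)))
  p <- p / sum(p)
  list(E_ads_B = sum(p * map$E), P = p)
}

#' Average an energy over crystal facets
#'
#' Weighted arithmetic mean of per-facet adsorption energies (equal weights by
#' default: all facets are assumed to contribute equally to the particle
#' surface).
#'
#' @param per_facet Named numeric vector of per-facet energies.
#' @param weights Named weights over the same facets; default equal.
#' @return The weighted mean energy.
#' @export
facet_average <- function(per_facet, weights = NULL) {
  stopifnot(length(per_facet) >= 1)
  if (is.null(weights)) {
    weights <- rep(1 / length(per_facet), length(per_facet))
    names(weights) <- names(per_facet)
  }
  if (!is.null(names(weights)) && !is.null(names(per_facet))) {
    missing <- setdiff(names(weights)[weights > 0], names(per_facet))
    if (length(missing) > 0) {
      stop("missing facet value(s) with nonzero weight: ",
           paste(missing, collapse = ", "))
    }
    weights <- weights[names(per_facet)]
    weights[is.na(weights)] <- 0
  }
  sum(weights * per_facet) / sum(weights)
}

#' Lowest-energy pose and contact footprint
#'
#' Extracts the global (theta, phi, z) energy minimum from an orientation map
#' (ties broken deterministically by grid order), refines the separation by
#' local minimization, and returns the posed protein, the contact list
#' (residues within 0.5 nm of the particle surface, sorted by SSD), and
#' optionally writes a PDB of the pose with a particle placeholder.
#'
#' @inheritParams orientation_map
#' @param map The `ns_adsorption_map` for this protein/particle/facet.
#' @param pdb_path Optional path; when given, the pose is written as a PDB
#'   with the CG beads as pseudo-atoms plus a particle placeholder.
#' @return A list with `state` (the minimizing [configuration_state()]),
#'   `energy` (kT at the minimum), `protein` (posed `ns_protein` in the
#'   particle frame), and `contacts` (tibble: `residue`, `bead`, `h`).
#' @export
lowest_energy_pose <- function(map, protein, np, med, tables,
                               facet = attr(map, "facet"),
                               hamaker = NULL,
                               materials = default_material_db(),
                               solvent_id = "water",
                               slab_thickness = 1.1,
                               pdb_path = NULL) {
  stopifnot(inherits(map, "ns_adsorption_map"))
  i <- which.min(map$U_min)[1]
  theta <- map$theta[i]; phi <- map$phi[i]
  rot <- rotate_protein(protein, theta, phi)
  rot$beads <- .ensure_material(rot$beads)
  if (is.null(hamaker)) {
    hamaker <- .hamaker_map(rot, np, med, materials, solvent_id)
  }
  Uf <- .profile_fun(rot, np, med, tables, facet, hamaker, slab_thickness)
  opt <- stats::optimize(Uf, c(max(1e-3, map$z_min[i] - 0.05),
                               map$z_min[i] + 0.05), tol = 1e-8)
  z <- opt$minimum
  pos <- sweep(as.matrix(rot$beads[, c("x", "y", "z")]), 2, rot$com)
  posed <- rot
  posed$beads$x <- pos[, 1]; posed$beads$y <- pos[, 2]
  posed$beads$z <- pos[, 3] + z
  posed$com <- c(0, 0, z)
  h_i <- if (np$shape == "sphere") {
    sqrt(posed$beads$x^2 + posed$beads$y^2 + posed$beads$z^2) - np$radius
  } else {
    posed$beads$z
  }
  contacts <- tibble::tibble(residue = posed$beads$residue,
                             bead = posed$beads$bead, h = h_i) |>
    dplyr::filter(.data$h < 0.5) |>
    dplyr::arrange(.data$h)
  if (!is.null(pdb_path)) {
    np_center <- if (np$shape == "sphere") c(0, 0, 0) else c(0, 0, -1)
    write_cg_pdb(posed, pdb_path, np_center = np_center)
  }
  list(state = configuration_state(theta, phi, z),
       energy = opt$objective, protein = posed, contacts = contacts)
}

#' Full adsorption calculation for one protein on one particle
#'
#' Runs the orientation scan on every facet of the particle, forms the simple
#' (E_ads^A) and Boltzmann (E_ads^B) orientation averages per facet, and
#' combines facets by their weights. Energies are reported in kT at the
#' medium temperature and in kJ/mol.
#'
#' @inheritParams orientation_map
#' @return An object of class `ns_adsorption`: a list with `per_facet` (tibble
#'   of per-facet E_ads^A/E_ads^B), `E_ads_A`, `E_ads_B` (facet-averaged, kT),
#'   `maps` (named list of `ns_adsorption_map`), `best` (lowest-energy pose
#'   over facets) and metadata. Supports [generics::tidy()],
#'   [generics::glance()] and [ggplot2::autoplot()] on its maps.
#' @examples
#' \donttest{
#' toy <- toy_protein(2, "dumbbell", c("LYS", "ALA"))
#' lib <- synth_pmf_library(c("LYS", "ALA"), facets = "110", seed = 7)
#' np <- nanoparticle("slab", zeta_mV = -25, facets = "110")
#' fit <- adsorb_protein(toy$protein, np, medium(), lib,
#'                       grid = orientation_grid(30))
#' glance(fit)
#' }
#' @export
adsorb_protein <- function(protein, np, med, tables,
                           grid = orientation_grid(5),
                           hamaker = NULL,
                           materials = default_material_db(),
                           solvent_id = "water",
                           slab_thickness = 1.1, ...) {
  maps <- purrr::map(np$facets, function(f) {
    orientation_map(protein, np, med, tables, grid = grid, facet = f,
                    hamaker = hamaker, materials = materials,
                    solvent_id = solvent_id,
                    slab_thickness = slab_thickness, ...)
  })
  names(maps) <- np$facets
  per_facet <- purrr::imap_dfr(maps, function(m, f) {
    tibble::tibble(facet = f,
                   E_ads_A = average_simple(m),
                   E_ads_B = average_boltzmann(m)$E_ads_B,
                   U_min = min(m$U_min))
  })
  kj <- kT_kjmol(med$temperature)
  E_A <- facet_average(stats::setNames(per_facet$E_ads_A, per_facet$facet),
                       np$facet_weights)
  E_B <- facet_average(stats::setNames(per_facet$E_ads_B, per_facet$facet),
                       np$facet_weights)
  best_facet <- per_facet$facet[which.min(per_facet$U_min)[1]]
  best <- lowest_energy_pose(maps[[best_facet]], protein, np, med, tables,
                             facet = best_facet, hamaker = hamaker,
                             materials = materials, solvent_id = solvent_id,
                             slab_thickness = slab_thickness)
  structure(
    list(protein_id = protein$source_id, np = np, medium = med,
         per_facet = per_facet, maps = maps,
         E_ads_A = E_A, E_ads_B = E_B,
         E_ads_A_kJmol = E_A * kj, E_ads_B_kJmol = E_B * kj,
         best_facet = best_facet, best = best),
    class = "ns_adsorption"
  )
}

#' @export
print.ns_adsorption <- function(x, ...) {
  cat(sprintf(
    "<ns_adsorption> %s on %s %s\n  E_ads^A = %.3f kT (%.2f kJ/mol), E_ads^B = %.3f kT (%.2f kJ/mol)\n  best pose: facet %s, theta %.2f, phi %.2f, z %.3f nm (%.2f kT)\n",
    x$protein_id, x$np$material_id, x$np$shape,
    x$E_ads_A, x$E_ads_A_kJmol, x$E_ads_B, x$E_ads_B_kJmol,
    x$best_facet, x$best$state$theta, x$best$state$phi, x$best$state$z,
    x$best$energy))
  invisible(x)
}
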