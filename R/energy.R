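#' Screened electrostatic bead-particle energy
#'
#' Linearized Poisson-Boltzmann (Debye-Hueckel) interaction of a point charge
#' z_bead with a surface held at the zeta potential phi_s:
#' `U = z e phi_s exp(-kappa h) R_NP/(R_NP + h)` (curvature factor 1 for a
#' slab), expressed in kT. The sign follows `sign(z * phi_s)`; the magnitude
#' decays monotonically with h. At 298.15 K a unit charge at contact with a
#' -25.69 mV surface is -1.00 kT (e * 25.69 mV = kT).
#'
#' @param charge Bead charge in elementary charge units (vectorized, recycled
#'   against `h`).
#' @param np An [nanoparticle()] object.
#' @param med An [medium()] object.
#' @param h SSD in nm, >= 0 (vectorized).
#' @return Energy in kT.
#' @export
electrostatic_energy <- function(charge, np, med, h) {
  stopifnot(inherits(np, "ns_nanoparticle"), inherits(med, "ns_medium"))
  if (any(h < 0)) stop("electrostatic_energy requires h >= 0")
  if (all(charge == 0) || np$zeta_mV == 0) {
    return(numeric(max(length(h), length(charge))) )
  }
  d <- suppressWarnings(medium_derived(med))
  kappa <- d$inv_debye_length
  phi_V <- np$zeta_mV / 1000
  u0 <- charge * .const$e * phi_V / kT_joule(med$temperature)
  curv <- if (np$shape == "sphere") np$radius / (np$radius + h) else 1
  u0 * exp(-kappa * h) * curv
}

#' Total bead-particle interaction energy
#'
#' Combines the three terms of the model at a surface separation distance `h`
#' (particle surface to bead centre, nm). Inside the cutoff (`h < r_c`) the
#' nonbonded part is the tabulated surface potential plus the core
#' double-counting correction; at and beyond `r_c` it is the Hamaker core
#' potential. The screened electrostatic term applies everywhere. The two
#' nonbonded branches are continuous at `r_c` within the 0.25 kT
#' zero-referencing tolerance of the tables.
#'
#' @param bead One row of a bead registry (or a list with `charge`, `radius`,
#'   `pmf_name`).
#' @param table The [pmf_table()] for this bead and the particle facet.
#' @param A Hamaker constant ([hamaker_constant()] object or joule value) for
#'   the bead/particle/solvent triple.
#' @param np An [nanoparticle()] object.
#' @param med An [medium()] object.
#' @param h SSD in nm (vectorized).
#' @param slab_thickness Parametrization slab thickness in nm.
#' @return Energy in kT, same length as `h`.
#' @export
bead_energy <- function(bead, table, A, np, med, h, slab_thickness = 1.1) {
  stopifnot(inherits(table, "ns_pmf"))
  if (!identical(as.character(table$facet), "any") &&
      !(as.character(table$facet) %in% as.character(np$facets))) {
    stop("facet mismatch: table is for facet ", table$facet,
         " but particle exposes ", paste(np$facets, collapse = "/"))
  }
  r_c <- table$r_c
  # surface gap for the dispersion closed forms; floored for stability deep
  # inside the excluded-volume wall where the PMF cap dominates anyway
  gap <- pmax(h - bead$radius, 0.01)
  u <- numeric(length(h))
  inner <- h < r_c
  if (any(inner)) {
    u[inner] <- surface_pmf_eval(table, h[inner]) +
      core_correction(A, np$shape, bead_radius = bead$radius,
                      h = pmin(gap[inner], r_c - bead$radius - 1e-9),
                      np_radius = np$radius, slab_thickness = slab_thickness,
                      r_c = r_c, temperature = med$temperature)
  }
  if (any(!inner)) {
    u[!inner] <- core_potential(A, np$shape, bead_radius = bead$radius,
                                h = gap[!inner], np_radius = np$radius,
                                temperature = med$temperature)
  }
  u + electrostatic_energy(bead$charge, np, med, h)
}

#' Interaction energy of a whole protein in one configuration
#'
#' Rotates the protein to `(theta, phi)`, places its centre of mass at
#' separation `z` from the particle (COM-COM distance for a sphere, height
#' above the surface plane for a slab), computes each bead's surface
#' separation distance and sums [bead_energy()] over all beads. Beads driven
#' into the excluded-volume wall contribute the capped wall energy rather than
#' raising an error.
#'
#' @param protein An [cg_protein()] object (initial orientation).
#' @param np An [nanoparticle()] object.
#' @param med An [medium()] object.
#' @param tables An [pmf_library()] covering every bead `pmf_name` for the
#'   facet.
#' @param state An [configuration_state()].
#' @param facet Facet label selecting the tables (default: first particle
#'   facet).
#' @param hamaker Named list of Hamaker constants keyed by bead material_id;
#'   computed from `materials` if omitted.
#' @param materials Material database (see [default_material_db()]).
#' @param solvent_id Material id of the solvent in `materials`.
#' @param slab_thickness Parametrization slab thickness in nm.
#' @return Total energy in kT (scalar).
#' @export
configuration_energy <- function(protein, np, med, tables, state,
                                 facet = np$facets[1],
                                 hamaker = NULL,
                                 materials = default_material_db(),
                                 solvent_id = "water",
                                 slab_thickness = 1.1) {
  stopifnot(inherits(protein, "ns_protein"), inherits(state, "ns_state"))
  rot <- rotate_protein(protein, state$theta, state$phi)
  sum(.placed_energy(rot, np, med, tables, state$z, facet,
                     hamaker = hamaker, materials = materials,
                     solvent_id = solvent_id,
                     slab_thickness = slab_thickness))
}

# Hamaker constants per material id present in the protein
.hamaker_map <- function(protein, np, med, materials, solvent_id) {
  ids <- unique(protein$beads$material_id)
  solvent <- materials[[solvent_id]]
  np_mat <- materials[[np$material_id]]
  if (is.null(solvent)) stop("unknown solvent material: ", solvent_id)
  if (is.null(np_mat)) stop("unknown particle material: ", np$material_id)
  out <- lapply(ids, function(id) {
    m <- materials[[id]]
    if (is.null(m)) stop("unknown bead material: ", id)
    hamaker_constant(m, np_mat, solvent, med$temperature)
  })
  names(out) <- ids
  out
}

# per-bead energies of an already-rotated protein with COM at separation z
.placed_energy <- function(rot, np, med, tables, z, facet,
                           hamaker = NULL, materials = default_material_db(),
                           solvent_id = "water", slab_thickness = 1.1) {
  b <- .ensure_material(rot$beads)
  if (is.null(hamaker)) {
    rot2 <- rot; rot2$beads <- b
    hamaker <- .hamaker_map(rot2, np, med, materials, solvent_id)
  }
  pos <- as.matrix(b[, c("x", "y", "z")])
  pos <- sweep(pos, 2, rot$com) # bead offsets from the COM
  h_i <- if (np$shape == "sphere") {
    sqrt(pos[, 1]^2 + pos[, 2]^2 + (pos[, 3] + z)^2) - np$radius
  } else {
    z + pos[, 3]
  }
  h_i <- pmax(h_i, 1e-6) # beads past the wall contribute the capped energy
  vapply(seq_len(nrow(b)), function(i) {
    tab <- pmf_lookup(tables, b$pmf_name[i], facet)
    bead_energy(b[i, ], tab, hamaker[[b$material_id[i]]], np, med, h_i[i],
                slab_thickness = slab_thickness)
  }, numeric(1))
}

# fill the material_id column from the default registry when absent
.ensure_material <- function(beads) {
  if (!"material_id" %in% names(beads)) {
    beads$material_id <-
      registry_lookup(default_bead_registry(), beads$bead)$material_id
  }
  beads
}
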