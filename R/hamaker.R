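# Lifshitz-approximation Hamaker constants and Hamaker-geometry dispersion
# potentials for the long-range particle-core interaction.

# Single-relaxation response of material j against solvent 3 on the imaginary
# frequency axis: Delta_j(i nu) = amp * w^2 / (nu^2 + w^2). For a dielectric
# with eps(i nu) = 1 + (n^2 - 1)/(1 + nu^2/nu_e^2) and effective nu_e =
# sqrt(nu_j nu_3): amp = (n_j^2 - n_3^2)/(n_j^2 + n_3^2),
# w = nu_e sqrt((n_j^2 + n_3^2)/2). For a conductor, eps(i nu) = 1 +
# nu_p^2/nu^2: amp = 1, w = nu_p/sqrt(2).
.lifshitz_mode <- function(m, solvent) {
  if (m$class == "conducting") {
    list(amp = 1, w = m$frequency / sqrt(2), delta0 = 1)
  } else {
    n2 <- m$refractive_index^2
    n3 <- solvent$refractive_index^2
    nu_e <- sqrt(m$frequency * solvent$frequency)
    list(
      amp = (n2 - n3) / (n2 + n3),
      w = nu_e * sqrt((n2 + n3) / 2),
      delta0 = (m$dielectric - solvent$dielectric) /
        (m$dielectric + solvent$dielectric)
    )
  }
}

#' Hamaker constant from the Lifshitz two-term approximation
#'
#' For two dielectric half-spaces 1 and 2 across solvent 3 this reduces to the
#' standard textbook form: a zero-frequency term
#' (3/4) kT \[(e1-e3)/(e1+e3)\]\[(e2-e3)/(e2+e3)\] plus a dispersion term in the
#' refractive indices,
#' (3 h nu_e / 8 sqrt(2)) (n1^2-n3^2)(n2^2-n3^2) /
#' \[sqrt(n1^2+n3^2) sqrt(n2^2+n3^2) (sqrt(n1^2+n3^2)+sqrt(n2^2+n3^2))\].
#' A conducting material 2 enters through its plasma frequency (amplitude 1,
#' relaxation frequency nu_p/sqrt(2)); its zero-frequency reflection
#' coefficient is 1. Unlike dielectric absorption frequencies are mixed as
#' nu_e = sqrt(nu_j nu_3). The constant vanishes exactly when either material
#' matches the solvent, and is symmetric in materials 1 and 2.
#'
#' @param m1,m2,m3 [hamaker_material()] objects: bead material, particle
#'   material, solvent. The solvent must be dielectric.
#' @param temperature Temperature in kelvin for the entropic zero-frequency
#'   term and the kT conversion.
#' @return An object of class `ns_hamaker` with elements `A_J` (joule), `A_kT`
#'   (units of kT at `temperature`), `static_J`, `dispersion_J`, and the
#'   material ids.
#' @examples
#' db <- default_material_db()
#' hamaker_constant(db$polystyrene, db$polystyrene, db$water, 298)
#' @export
hamaker_constant <- function(m1, m2, m3, temperature = 300) {
  stopifnot(inherits(m1, "ns_material"), inherits(m2, "ns_material"),
            inherits(m3, "ns_material"))
  if (m3$class == "conducting") {
    stop("a conducting solvent is not supported")
  }
  d1 <- .lifshitz_mode(m1, m3)
  d2 <- .lifshitz_mode(m2, m3)
  static_J <- 0.75 * .const$kB * temperature * d1$delta0 * d2$delta0
  dispersion_J <- (3 * .const$hplanck / 8) * d1$amp * d2$amp *
    d1$w * d2$w / (d1$w + d2$w)
  A_J <- static_J + dispersion_J
  structure(
    list(A_J = A_J, A_kT = A_J / kT_joule(temperature),
         static_J = static_J, dispersion_J = dispersion_J,
         materials = c(m1$material_id, m2$material_id, m3$material_id),
         temperature = temperature),
    class = "ns_hamaker"
  )
}

#' @export
print.ns_hamaker <- function(x, ...) {
  cat(sprintf("<ns_hamaker> A(%s|%s|%s) = %.3e J = %.3g kT\n",
              x$materials[1], x$materials[3], x$materials[2], x$A_J, x$A_kT))
  invisible(x)
}

as_hamaker_J <- function(A) {
  if (inherits(A, "ns_hamaker")) A$A_J else as.numeric(A)
}

# sphere (radius R) -- half-space, surface gap s (nm); energy in joule units
# of A. Hamaker 1937 closed form.
.u_sphere_halfspace <- function(A_J, R, s) {
  -(A_J / 6) * (R / s + R / (s + 2 * R) + log(s / (s + 2 * R)))
}

# two spheres R1, R2, centre separation d (nm)
.u_two_spheres <- function(A_J, R1, R2, d) {
  p <- d^2 - (R1 + R2)^2
  q <- d^2 - (R1 - R2)^2
  -(A_J / 6) * (2 * R1 * R2 / p + 2 * R1 * R2 / q + log(p / q))
}

#' Dispersion potential between a bead and the particle core
#'
#' The Hamaker-geometry closed forms: a sphere against a half-space for a
#' flat-slab particle, the two-sphere formula (centre separation
#' `R_NP + bead_radius + h`) for a spherical particle. `h` is the
#' surface-to-surface gap in nm. The result is non-positive for `A > 0`,
#' scales linearly in `A`, and decays to zero at large `h` (as h^-3 for the
#' half-space form).
#'
#' @param A Hamaker constant: an [hamaker_constant()] object or a plain value
#'   in joule.
#' @param shape `"sphere"` or `"slab"` (particle geometry).
#' @param bead_radius Bead radius R_AA in nm.
#' @param h Surface-to-surface gap in nm (> 0); vectorized.
#' @param np_radius Particle radius R_NP in nm (spheres).
#' @param temperature Kelvin, for the kT conversion.
#' @return Energy in kT, same length as `h`.
#' @examples
#' core_potential(1e-20, "slab", bead_radius = 10, h = 1, temperature = 298)
#' @export
core_potential <- function(A, shape = c("sphere", "slab"), bead_radius, h,
                           np_radius = NULL, temperature = 300) {
  shape <- match.arg(shape)
  A_J <- as_hamaker_J(A)
  if (any(h <= 0)) stop("core_potential requires h > 0 (gap in nm)")
  stopifnot(bead_radius > 0)
  u <- if (shape == "slab" || is.infinite(np_radius %||% Inf)) {
    .u_sphere_halfspace(A_J, bead_radius, h)
  } else {
    if (!isTRUE(np_radius > 0)) stop("sphere geometry requires np_radius > 0")
    .u_two_spheres(A_J, np_radius, bead_radius, np_radius + bead_radius + h)
  }
  u / kT_joule(temperature)
}

#' Double-counting correction for the core term inside the PMF region
#'
#' Below the cutoff `r_c` the tabulated surface potential already contains the
#' bead's nonbonded interaction with the flat slab of material used in its
#' parametrization (thickness ~1.0-1.2 nm). What the tabulated term misses is
#' the dispersion attraction of the rest of the particle body, so the
#' correction returned here is the dispersion energy of the bead with the
#' whole particle minus that with the parametrization slab. For a flat
#' particle this telescopes to the sphere-half-space form evaluated at
#' `h + slab_thickness`; for a spherical particle it is the two-sphere energy
#' minus the finite-slab energy `U_hs(h) - U_hs(h + t)`. As
#' `slab_thickness -> 0` the correction tends to [core_potential()].
#'
#' @inheritParams core_potential
#' @param slab_thickness Thickness of the parametrization slab in nm
#'   (default 1.1).
#' @param r_c PMF cutoff in nm; the correction only applies for `h_ssd < r_c`
#'   (checked against `h + bead_radius`, the surface separation distance).
#' @return Energy in kT, same length as `h`.
#' @export
core_correction <- function(A, shape = c("sphere", "slab"), bead_radius, h,
                            np_radius = NULL, slab_thickness = 1.1,
                            r_c = 1.0, temperature = 300) {
  shape <- match.arg(shape)
  A_J <- as_hamaker_J(A)
  if (any(h <= 0)) stop("core_correction requires h > 0 (gap in nm)")
  if (any(h + bead_radius >= r_c)) {
    stop("core_correction applies only inside the PMF region (h_ssd < r_c)")
  }
  stopifnot(slab_thickness >= 0)
  kT <- kT_joule(temperature)
  if (shape == "slab" || is.infinite(np_radius %||% Inf)) {
    .u_sphere_halfspace(A_J, bead_radius, h + slab_thickness) / kT
  } else {
    slab_part <- .u_sphere_halfspace(A_J, bead_radius, h) -
      .u_sphere_halfspace(A_J, bead_radius, h + slab_thickness)
    (.u_two_spheres(A_J, np_radius, bead_radius,
                    np_radius + bead_radius + h) - slab_part) / kT
  }
}
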