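#' Define the aqueous medium
#'
#' The solvent enters the model implicitly: through its relative permittivity,
#' its temperature, and the ionic composition that screens the electrostatic
#' term. The default is physiological saline, 0.15 M monovalent salt at 300 K.
#'
#' @param species A data frame with columns `conc` (mol/L) and `z` (ion
#'   valence), one row per ionic species. The composition must be
#'   electroneutral.
#' @param dielectric Relative permittivity of the solvent (dimensionless,
#'   > 1). Default 78.4 (water near room temperature).
#' @param temperature Absolute temperature in kelvin.
#' @return An object of class `ns_medium`.
#' @examples
#' medium()                       # 0.15 M KCl-like saline, 300 K
#' medium_derived(medium())
#' @export
medium <- function(species = saline_species(0.15),
                   dielectric = 78.4,
                   temperature = 300) {
  species <- tibble::as_tibble(species)
  stopifnot(all(c("conc", "z") %in% names(species)))
  if (any(species$conc < 0)) stop("ion concentrations must be >= 0")
  if (!isTRUE(dielectric > 1)) stop("dielectric must be > 1")
  if (!isTRUE(temperature > 0)) stop("temperature must be > 0 K")
  net <- sum(species$conc * species$z)
  if (abs(net) > 1e-8 * max(sum(abs(species$conc * species$z)), 1e-12)) {
    stop("ionic composition is not electroneutral (net charge ", net, " M e)")
  }
  structure(
    list(species = species, dielectric = dielectric,
         temperature = temperature),
    class = "ns_medium"
  )
}

#' @rdname medium
#' @param conc Total salt concentration in mol/L for a symmetric monovalent
#'   salt.
#' @export
saline_species <- function(conc = 0.15) {
  tibble::tibble(conc = c(conc, conc), z = c(1, -1))
}

#' Derived electrostatic screening quantities
#'
#' Computes, from the medium composition, the ionic strength
#' I = 1/2 sum c_i z_i^2 (mol/L), the Bjerrum length
#' lambda_B = e^2 / (4 pi eps0 eps k_B T) (nm), and the inverse Debye length
#' kappa = sqrt(8 pi lambda_B N_A 1e3 I) (1/nm). At 0.15 M monovalent salt in
#' water at 298.15 K the Debye length 1/kappa is about 0.78 nm.
#'
#' A salt-free medium returns `kappa = 0` (the unscreened limit) with a
#' warning rather than an error.
#'
#' @param med An [medium()] object.
#' @return A one-row tibble with columns `ionic_strength` (mol/L),
#'   `bjerrum_length` (nm), `inv_debye_length` (1/nm), `debye_length` (nm).
#' @export
medium_derived <- function(med) {
  stopifnot(inherits(med, "ns_medium"))
  I <- 0.5 * sum(med$species$conc * med$species$z^2)
  lB_m <- .const$e^2 /
    (4 * pi * .const$eps0 * med$dielectric * .const$kB * med$temperature)
  lB <- lB_m * 1e9
  if (I == 0) {
    warning("ionic strength is zero: returning the unscreened limit kappa = 0")
    kappa <- 0
  } else {
    kappa_m <- sqrt(8 * pi * lB_m * .const$Navo * 1e3 * I) # 1/m
    kappa <- kappa_m * 1e-9
  }
  tibble::tibble(
    ionic_strength = I,
    bjerrum_length = lB,
    inv_debye_length = kappa,
    debye_length = if (kappa > 0) 1 / kappa else Inf
  )
}

#' @export
print.ns_medium <- function(x, ...) {
  d <- medium_derived(x)
  cat(sprintf(
    "<ns_medium> eps = %.3g, T = %.5g K, I = %.4g M, 1/kappa = %.3g nm\n",
    x$dielectric, x$temperature, d$ionic_strength, d$debye_length
  ))
  invisible(x)
}
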