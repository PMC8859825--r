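# broom-style tidiers for fitted adsorption objects.

#' Tidy an adsorption result
#'
#' `tidy()` returns one row per facet with the simple and Boltzmann
#' orientation averages; `glance()` returns a one-row summary with the
#' facet-averaged adsorption energies (kT and kJ/mol) and the best pose.
#'
#' @param x An `ns_adsorption` object from [adsorb_protein()].
#' @param ... Unused.
#' @return A tibble.
#' @export
tidy.ns_adsorption <- function(x, ...) {
  kj <- kT_kjmol(x$medium$temperature)
  dplyr::mutate(x$per_facet,
                protein = x$protein_id,
                E_ads_A_kJmol = .data$E_ads_A * kj,
                E_ads_B_kJmol = .data$E_ads_B * kj,
                .before = 1)
}

#' @rdname tidy.ns_adsorption
#' @export
glance.ns_adsorption <- function(x, ...) {
  tibble::tibble(
    protein = x$protein_id,
    shape = x$np$shape,
    radius_nm = x$np$radius,
    zeta_mV = x$np$zeta_mV,
    n_facets = length(x$maps),
    E_ads_A = x$E_ads_A,
    E_ads_B = x$E_ads_B,
    E_ads_A_kJmol = x$E_ads_A_kJmol,
    E_ads_B_kJmol = x$E_ads_B_kJmol,
    best_facet = x$best_facet,
    best_theta = x$best$state$theta,
    best_phi = x$best$state$phi,
    best_z_nm = x$best$state$z,
    best_energy = x$best$energy
  )
}

#' @rdname tidy.ns_adsorption
#' @export
tidy.ns_adsorption_map <- function(x, ...) {
  tibble::as_tibble(x)
}
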