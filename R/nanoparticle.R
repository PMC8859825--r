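#' Define a nanoparticle
#'
#' The particle is a rigid homogeneous body: either a sphere of radius `R_NP`
#' or a flat slab (half-space). Its surface potential is taken from the
#' measured zeta potential, and its crystallographic facets (fcc 100/110/111)
#' select which tabulated surface potentials apply; facet weights give the
#' relative abundance of each facet on the particle surface and must sum to 1
#' (equal weights by default, assuming all facets contribute equally to
#' adsorption).
#'
#' @param shape `"sphere"` or `"slab"`.
#' @param radius Particle radius R_NP in nm (spheres only).
#' @param zeta_mV Surface (zeta) potential phi_s in millivolts.
#' @param facets Character vector of facet labels.
#' @param facet_weights Numeric weights, same length as `facets`, summing
#'   to 1. Default equal weights.
#' @param material_id Key into the dielectric material database used for
#'   Hamaker constants.
#' @return An object of class `ns_nanoparticle`.
#' @examples
#' nanoparticle("sphere", radius = 18, zeta_mV = -28.1)
#' @export
nanoparticle <- function(shape = c("sphere", "slab"),
                         radius = NULL,
                         zeta_mV = 0,
                         facets = c("100", "110", "111"),
                         facet_weights = NULL,
                         material_id = "silver") {
  shape <- match.arg(shape)
  if (shape == "sphere") {
    if (is.null(radius) || !isTRUE(radius > 0)) {
      stop("a sphere requires radius > 0 (nm)")
    }
  } else {
    radius <- Inf
  }
  facets <- as.character(facets)
  if (is.null(facet_weights)) {
    facet_weights <- rep(1 / length(facets), length(facets))
  }
  if (length(facet_weights) != length(facets)) {
    stop("facet_weights must match facets in length")
  }
  if (abs(sum(facet_weights) - 1) > 1e-9) stop("facet weights must sum to 1")
  structure(
    list(shape = shape, radius = radius, zeta_mV = zeta_mV,
         facets = facets,
         facet_weights = stats::setNames(facet_weights, facets),
         material_id = material_id),
    class = "ns_nanoparticle"
  )
}

#' @export
print.ns_nanoparticle <- function(x, ...) {
  cat(sprintf(
    "<ns_nanoparticle> %s%s, zeta = %.3g mV, facets %s (%s), material %s\n",
    x$shape,
    if (x$shape == "sphere") sprintf(" R = %.3g nm", x$radius) else "",
    x$zeta_mV,
    paste(x$facets, collapse = "/"),
    paste(signif(x$facet_weights, 3), collapse = "/"),
    x$material_id
  ))
  invisible(x)
}
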