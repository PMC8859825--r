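#' Dielectric material description for Hamaker constants
#'
#' Lifshitz-style Hamaker constants are computed from the static relative
#' permittivity, the visible refractive index, and a characteristic electronic
#' frequency: the main UV absorption frequency for dielectrics, the plasma
#' frequency for conductors. Conducting materials carry no meaningful static
#' permittivity or refractive index (their zero-frequency response is
#' metallic), so those fields are ignored for `class = "conducting"`.
#'
#' @param material_id Identifier string.
#' @param class `"dielectric"` or `"conducting"`.
#' @param dielectric Static relative permittivity (dielectrics).
#' @param refractive_index Visible refractive index, >= 1 (dielectrics).
#' @param frequency Characteristic electronic frequency in Hz (> 0).
#' @return An object of class `ns_material`.
#' @examples
#' hamaker_material("water", "dielectric", 78.4, 1.333, 3.0e15)
#' @export
hamaker_material <- function(material_id, class = c("dielectric", "conducting"),
                             dielectric = NA_real_,
                             refractive_index = NA_real_,
                             frequency) {
  class <- match.arg(class)
  if (!isTRUE(frequency > 0)) stop("frequency must be > 0 Hz")
  if (class == "dielectric") {
    if (!isTRUE(dielectric > 0)) stop("dielectric permittivity must be > 0")
    if (!isTRUE(refractive_index >= 1)) stop("refractive index must be >= 1")
  }
  structure(
    list(material_id = material_id, class = class, dielectric = dielectric,
         refractive_index = refractive_index, frequency = frequency),
    class = "ns_material"
  )
}

#' Packaged dielectric material database
#'
#' Default constants for the materials used in the silver-nanoparticle
#' parametrization: water (eps 78.4, n 1.333, nu_e 3.0e15 Hz), a generic
#' amino-acid bead material (protein-like dielectric), carbohydrate and lipid
#' fragments, polystyrene (the classic textbook benchmark triple), and
#' zero-valent silver as a conductor with plasma frequency 2.18e15 Hz
#' (9.0 eV). Values are editable via the YAML material file.
#'
#' @return A named list of [hamaker_material()] objects.
#' @export
default_material_db <- function() {
  list(
    water = hamaker_material("water", "dielectric", 78.4, 1.333, 3.0e15),
    amino_acid = hamaker_material("amino_acid", "dielectric", 4.0, 1.50, 3.0e15),
    carbohydrate = hamaker_material("carbohydrate", "dielectric", 3.5, 1.49, 3.0e15),
    lipid = hamaker_material("lipid", "dielectric", 2.0, 1.44, 3.0e15),
    polystyrene = hamaker_material("polystyrene", "dielectric", 2.55, 1.557, 3.0e15),
    silver = hamaker_material("silver", "conducting", frequency = 2.18e15),
    gold = hamaker_material("gold", "conducting", frequency = 2.08e15)
  )
}

#' Read / write a material database file
#'
#' Structured key-value text (YAML) keyed by `material_id`, each entry with
#' `class`, `dielectric`, `refractive_index`, `frequency`.
#'
#' @param path File path.
#' @return `read_material_db()` returns a named list of materials;
#'   `write_material_db()` returns `path` invisibly.
#' @export
read_material_db <- function(path) {
  raw <- yaml::read_yaml(path)
  if (length(raw) == 0) stop("empty material database: ", path)
  purrr::imap(raw, function(entry, nm) {
    hamaker_material(nm, entry$class,
                     dielectric = as.numeric(entry$dielectric %||% NA),
                     refractive_index = as.numeric(entry$refractive_index %||% NA),
                     frequency = as.numeric(entry$frequency))
  })
}

#' @rdname read_material_db
#' @param db Named list of [hamaker_material()] objects.
#' @export
write_material_db <- function(db, path) {
  out <- purrr::map(db, function(m) {
    e <- list(class = m$class, frequency = m$frequency)
    if (m$class == "dielectric") {
      e$dielectric <- m$dielectric
      e$refractive_index <- m$refractive_index
    }
    e
  })
  names(out) <- purrr::map_chr(db, "material_id")
  yaml::write_yaml(out, path, precision = 12)
  invisible(path)
}
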