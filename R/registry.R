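#' Bead parameter registry
#'
#' The coarse-grained force field assigns one bead per residue (or per
#' carbohydrate / lipid fragment). Each bead carries the net charge at neutral
#' pH (elementary charge units), an effective bead radius `R_AA` (nm) used by
#' the dispersion term, a `material_id` pointing into the dielectric material
#' database, and a `pmf_name`: the bead name under which its short-range
#' surface potential is tabulated. For glycine no side-chain potential exists,
#' so its `pmf_name` is `ALA` while its position falls back to the C-alpha
#' atom.
#'
#' `default_bead_registry()` returns the packaged 32-bead registry covering
#' the 20 canonical amino acids (CHARMM residue naming, `HIS` aliased to the
#' neutral `HSD` tautomer), the protonation variants `HSE`, `HSP`, `ASPP`,
#' `GLUP`, seven carbohydrate fragments including `BGALNA`, and the
#' dimethyl-phosphate lipid fragment `DMP`. Charges are formal charges at
#' pH 7; radii are effective side-chain-analogue radii and are meant to be
#' edited for other parametrizations via the YAML registry file.
#'
#' @return A tibble with columns `name`, `charge` (e), `radius` (nm),
#'   `material_id`, `pmf_name`.
#' @seealso [read_bead_registry()], [write_bead_registry()]
#' @examples
#' default_bead_registry()
#' @export
default_bead_registry <- function() {
  reg <- tibble::tribble(
    ~name,     ~charge, ~radius, ~material_id,   ~pmf_name,
    "ALA",      0,       0.26,   "amino_acid",   "ALA",
    "ARG",      1,       0.35,   "amino_acid",   "ARG",
    "ASN",      0,       0.30,   "amino_acid",   "ASN",
    "ASP",     -1,       0.29,   "amino_acid",   "ASP",
    "ASPP",     0,       0.29,   "amino_acid",   "ASPP",
    "CYS",      0,       0.28,   "amino_acid",   "CYS",
    "GLN",      0,       0.31,   "amino_acid",   "GLN",
    "GLU",     -1,       0.31,   "amino_acid",   "GLU",
    "GLUP",     0,       0.31,   "amino_acid",   "GLUP",
    "GLY",      0,       0.23,   "amino_acid",   "ALA",
    "HSD",      0,       0.33,   "amino_acid",   "HSD",
    "HSE",      0,       0.33,   "amino_acid",   "HSE",
    "HSP",      1,       0.33,   "amino_acid",   "HSP",
    "ILE",      0,       0.31,   "amino_acid",   "ILE",
    "LEU",      0,       0.31,   "amino_acid",   "LEU",
    "LYS",      1,       0.34,   "amino_acid",   "LYS",
    "MET",      0,       0.32,   "amino_acid",   "MET",
    "PHE",      0,       0.34,   "amino_acid",   "PHE",
    "PRO",      0,       0.29,   "amino_acid",   "PRO",
    "SER",      0,       0.26,   "amino_acid",   "SER",
    "THR",      0,       0.28,   "amino_acid",   "THR",
    "TRP",      0,       0.37,   "amino_acid",   "TRP",
    "TYR",      0,       0.35,   "amino_acid",   "TYR",
    "VAL",      0,       0.29,   "amino_acid",   "VAL",
    "BGALNA",   0,       0.38,   "carbohydrate", "BGALNA",
    "BGLCNA",   0,       0.38,   "carbohydrate", "BGLCNA",
    "AMAN",     0,       0.36,   "carbohydrate", "AMAN",
    "BMAN",     0,       0.36,   "carbohydrate", "BMAN",
    "AFUC",     0,       0.34,   "carbohydrate", "AFUC",
    "BGLC",     0,       0.36,   "carbohydrate", "BGLC",
    "AGAL",     0,       0.36,   "carbohydrate", "AGAL",
    "DMP",     -1,       0.33,   "lipid",        "DMP"
  )
  validate_bead_registry(reg)
}

validate_bead_registry <- function(reg) {
  stopifnot(is.data.frame(reg))
  need <- c("name", "charge", "radius", "material_id", "pmf_name")
  missing <- setdiff(need, names(reg))
  if (length(missing) > 0) {
    stop("bead registry is missing columns: ", paste(missing, collapse = ", "))
  }
  if (anyDuplicated(reg$name)) {
    stop("bead registry has duplicated names: ",
         paste(unique(reg$name[duplicated(reg$name)]), collapse = ", "))
  }
  if (any(!is.finite(reg$radius)) || any(reg$radius <= 0)) {
    stop("bead radii must be finite and > 0")
  }
  if (any(!is.finite(reg$charge))) stop("bead charges must be finite")
  tibble::as_tibble(reg)
}

#' Look up bead parameters by residue name
#'
#' Residue names are resolved through the alias map (`HIS -> HSD`) before the
#' registry lookup; an unknown residue is a hard error naming the residue.
#'
#' @param registry A bead registry tibble (see [default_bead_registry()]).
#' @param name Character vector of residue/bead names.
#' @return The matching registry rows, in the order of `name`.
#' @export
registry_lookup <- function(registry, name) {
  name <- resolve_bead_alias(name)
  idx <- match(name, registry$name)
  if (anyNA(idx)) {
    stop("no registry entry for residue(s): ",
         paste(unique(name[is.na(idx)]), collapse = ", "))
  }
  registry[idx, ]
}

# PDB residue-name aliases into the CHARMM bead naming convention.
resolve_bead_alias <- function(name) {
  alias <- c(HIS = "HSD", HID = "HSD", HIE = "HSE", HIP = "HSP",
             ASH = "ASPP", GLH = "GLUP", CYX = "CYS")
  hit <- name %in% names(alias)
  name[hit] <- alias[name[hit]]
  name
}

#' Read / write a bead registry file
#'
#' The registry is stored as structured key-value text (YAML): one entry per
#' bead name with `charge`, `radius`, `material_id` and optional `pmf_name`
#' (defaults to the bead's own name). The write/read pair round-trips to
#' identical parameters.
#'
#' @param path File path.
#' @return `read_bead_registry()` returns a registry tibble;
#'   `write_bead_registry()` returns `path` invisibly.
#' @export
read_bead_registry <- function(path) {
  raw <- yaml::read_yaml(path)
  if (length(raw) == 0) stop("empty bead registry file: ", path)
  reg <- purrr::imap_dfr(raw, function(entry, nm) {
    tibble::tibble(
      name = nm,
      charge = as.numeric(entry$charge),
      radius = as.numeric(entry$radius),
      material_id = as.character(entry$material_id),
      pmf_name = as.character(entry$pmf_name %||% nm)
    )
  })
  validate_bead_registry(reg)
}

#' @rdname read_bead_registry
#' @param registry A bead registry tibble.
#' @export
write_bead_registry <- function(registry, path) {
  registry <- validate_bead_registry(registry)
  out <- purrr::pmap(registry, function(name, charge, radius, material_id,
                                        pmf_name) {
    entry <- list(charge = charge, radius = radius, material_id = material_id)
    if (!identical(pmf_name, name)) entry$pmf_name <- pmf_name
    entry
  })
  names(out) <- registry$name
  yaml::write_yaml(out, path, precision = 12)
  invisible(path)
}
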