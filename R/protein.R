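#' Coarse-grained protein
#'
#' A rigid collection of one-per-residue beads. Each bead sits at the centroid
#' of the residue's side-chain heavy atoms (the tabulated surface potentials
#' describe side-chain analogues with the backbone replaced by hydrogen);
#' glycine, which has no side chain, uses its C-alpha position and borrows the
#' alanine surface potential. Positions are stored in nm; the centre of mass
#' is the unweighted centroid of the beads.
#'
#' @param beads A data frame with columns `residue` (integer index), `bead`
#'   (registry name), `pmf_name`, `charge`, `radius`, `x`, `y`, `z` (nm).
#' @param source_id Identifier of the originating structure.
#' @return An object of class `ns_protein` (also a tibble of beads, reachable
#'   via [tibble::as_tibble()]).
#' @export
cg_protein <- function(beads, source_id = "protein") {
  beads <- tibble::as_tibble(beads)
  need <- c("residue", "bead", "pmf_name", "charge", "radius", "x", "y", "z")
  if (!all(need %in% names(beads))) {
    stop("bead table is missing columns: ",
         paste(setdiff(need, names(beads)), collapse = ", "))
  }
  if (nrow(beads) < 1) stop("a protein needs at least one bead")
  xyz <- as.matrix(beads[, c("x", "y", "z")])
  if (!all(is.finite(xyz))) stop("bead positions must be finite")
  structure(
    list(beads = beads, com = colMeans(xyz), source_id = source_id),
    class = "ns_protein"
  )
}

#' @export
print.ns_protein <- function(x, ...) {
  cat(sprintf("<ns_protein> %s: %d beads, net charge %+g e\n",
              x$source_id, nrow(x$beads), sum(x$beads$charge)))
  invisible(x)
}

#' @export
as_tibble.ns_protein <- function(x, ...) x$beads

#' Coordinates of the beads as an n x 3 matrix (nm)
#' @param protein An [cg_protein()] object.
#' @return Numeric matrix with columns x, y, z.
#' @export
bead_coords <- function(protein) {
  as.matrix(protein$beads[, c("x", "y", "z")])
}

# residue names treated as solvent and silently dropped from PDB input
.solvent_resids <- c("HOH", "WAT", "TIP3", "TIP", "SOL", "DOD", "SPC")

#' Build a coarse-grained protein from a PDB structure
#'
#' Reads a standard PDB (first MODEL only, alternate location 'A' preferred),
#' groups atoms by residue, and places one bead per residue at the centroid of
#' its side-chain heavy atoms. Glycine has no side chain: its bead sits on the
#' C-alpha atom and is bound to the alanine surface potential through its
#' `pmf_name`. Protonation-variant residue names (e.g. `ASPP`, `HSP`) map to
#' their own registry entries; the protonation state is taken verbatim from
#' the input (prepared at pH 7), no titration is attempted.
#'
#' @param pdb Path to a PDB file, a character vector of PDB text lines, or a
#'   single string containing PDB text.
#' @param registry Bead registry tibble; see [default_bead_registry()].
#' @param source_id Identifier stored on the protein; defaults to the file
#'   name (or `"pdb_text"` for in-memory input).
#' @return An [cg_protein()] object. Coordinates are converted from angstrom
#'   to nm.
#' @examples
#' pdb <- toy_protein(3, geometry = "line", bead_names = c("ALA", "GLY", "LYS"))
#' p <- build_cg_protein(pdb$pdb_text)
#' nrow(as_tibble(p))
#' @export
build_cg_protein <- function(pdb, registry = default_bead_registry(),
                             source_id = NULL) {
  registry <- validate_bead_registry(registry)
  if (is.character(pdb) && length(pdb) == 1 && !grepl("\n", pdb) &&
      file.exists(pdb)) {
    path <- pdb
    if (is.null(source_id)) source_id <- basename(path)
  } else if (is.character(pdb)) {
    path <- tempfile(fileext = ".pdb")
    on.exit(unlink(path), add = TRUE)
    writeLines(if (length(pdb) == 1) strsplit(pdb, "\n")[[1]] else pdb, path)
    if (is.null(source_id)) source_id <- "pdb_text"
  } else {
    stop("pdb must be a file path or PDB text")
  }
  struct <- bio3d::read.pdb(path, multi = FALSE, verbose = FALSE)
  atoms <- tibble::as_tibble(struct$atom)
  if (nrow(atoms) == 0) stop("empty structure: no ATOM/HETATM records")
  atoms <- dplyr::filter(atoms, is.na(.data$alt) | .data$alt %in% c("", "A"))
  atoms <- dplyr::filter(atoms, !(.data$resid %in% .solvent_resids))
  if (nrow(atoms) == 0) stop("empty structure: no non-solvent residues")
  # drop hydrogens (element symbol if present, atom-name heuristic otherwise)
  is_h <- if ("elesy" %in% names(atoms) && !all(is.na(atoms$elesy))) {
    !is.na(atoms$elesy) & toupper(atoms$elesy) == "H"
  } else {
    grepl("^[0-9]*H", atoms$elety)
  }
  atoms <- atoms[!is_h, ]

  backbone <- c("N", "CA", "C", "O", "OXT", "OT1", "OT2")
  atoms$res_key <- paste(atoms$chain, atoms$resno, atoms$insert, sep = "_")
  res_order <- unique(atoms$res_key)

  beads <- purrr::map_dfr(seq_along(res_order), function(i) {
    ra <- atoms[atoms$res_key == res_order[i], ]
    resid <- ra$resid[1]
    bead_name <- resolve_bead_alias(resid)
    params <- tryCatch(registry_lookup(registry, bead_name),
                       error = function(e) stop(conditionMessage(e),
                                                " (residue ", i, ")",
                                                call. = FALSE))
    if (bead_name == "GLY") {
      sel <- ra[ra$elety == "CA", ]
      if (nrow(sel) == 0) {
        stop("glycine at residue index ", i, " has no C-alpha atom")
      }
    } else if (params$material_id == "amino_acid") {
      sel <- ra[!(ra$elety %in% backbone), ]
      if (nrow(sel) == 0) {
        stop("residue index ", i, " (", resid,
             ") has no side-chain heavy atoms")
      }
    } else {
      sel <- ra # carbohydrate / lipid fragments: all heavy atoms
    }
    tibble::tibble(
      residue = i, resid = resid, bead = params$name,
      pmf_name = params$pmf_name, charge = params$charge,
      radius = params$radius, material_id = params$material_id,
      x = mean(sel$x) / 10, y = mean(sel$y) / 10, z = mean(sel$z) / 10
    )
  })
  cg_protein(beads, source_id = source_id)
}

# 3x3 rotation matrix: R_z(phi) %*% R_y(theta)
rotation_matrix <- function(theta, phi) {
  ct <- cos(theta); st <- sin(theta)
  cp <- cos(phi); sp <- sin(phi)
  Ry <- matrix(c(ct, 0, st, 0, 1, 0, -st, 0, ct), 3, 3, byrow = TRUE)
  Rz <- matrix(c(cp, -sp, 0, sp, cp, 0, 0, 0, 1), 3, 3, byrow = TRUE)
  Rz %*% Ry
}

wrap_angles <- function(theta, phi) {
  # wrap phi into [0, 2pi); reflect theta into [0, pi]
  theta <- theta %% (2 * pi)
  if (theta > pi) {
    theta <- 2 * pi - theta
    phi <- phi + pi
  }
  c(theta = theta, phi = phi %% (2 * pi))
}

#' Rigid-body rotation of a protein
#'
#' Rotates all beads about the protein centre of mass by
#' `R_z(phi) %*% R_y(theta)` applied to the initial (input-file) frame. The
#' centre of mass and all pairwise bead distances are preserved; angles
#' outside the canonical ranges are wrapped.
#'
#' @param protein An [cg_protein()] object (in its initial orientation).
#' @param theta,phi Orientation angles in radians.
#' @return A rotated `ns_protein`.
#' @export
rotate_protein <- function(protein, theta, phi) {
  stopifnot(inherits(protein, "ns_protein"))
  ang <- wrap_angles(theta, phi)
  R <- rotation_matrix(ang["theta"], ang["phi"])
  xyz <- bead_coords(protein)
  centered <- sweep(xyz, 2, protein$com)
  rotated <- sweep(centered %*% t(R), 2, protein$com, `+`)
  out <- protein
  out$beads$x <- rotated[, 1]
  out$beads$y <- rotated[, 2]
  out$beads$z <- rotated[, 3]
  out
}

#' Orientation / separation state of the rigid protein
#'
#' @param theta,phi Orientation angles in radians (wrapped into
#'   `0 <= theta <= pi`, `0 <= phi < 2 pi`).
#' @param z Separation in nm: COM-COM distance for a spherical particle, COM
#'   height above the surface plane for a slab. Must be >= 0.
#' @return A named list of class `ns_state`.
#' @export
configuration_state <- function(theta = 0, phi = 0, z = 0) {
  if (!isTRUE(z >= 0)) stop("z must be >= 0")
  ang <- wrap_angles(theta, phi)
  structure(list(theta = unname(ang["theta"]), phi = unname(ang["phi"]),
                 z = z),
            class = "ns_state")
}

#' Write a coarse-grained protein as a PDB file
#'
#' Each bead becomes one pseudo-atom: `CB` for residues with a side chain,
#' `CA` for glycine, so the file re-imports through [build_cg_protein()] to
#' the same bead positions (to PDB coordinate precision, 1e-3 nm). An optional
#' nanoparticle placeholder atom (resname `NP`) marks the particle centre.
#'
#' @param protein An [cg_protein()] object.
#' @param path Output file path.
#' @param np_center Optional xyz (nm) of the nanoparticle centre to include as
#'   a placeholder HETATM.
#' @return `path`, invisibly.
#' @export
write_cg_pdb <- function(protein, path, np_center = NULL) {
  b <- protein$beads
  long <- nchar(b$bead) > 4
  if (any(long)) {
    warning("residue names truncated to 4 characters in PDB output: ",
            paste(unique(b$bead[long]), collapse = ", "))
  }
  fmt <- function(serial, name, resname, resno, x, y, z, het = FALSE) {
    sprintf("%-6s%5d %-4s %-4s%1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f",
            if (het) "HETATM" else "ATOM", serial, name,
            substr(resname, 1, 4), "A", resno, x * 10, y * 10, z * 10, 1, 0)
  }
  lines <- vapply(seq_len(nrow(b)), function(i) {
    fmt(i, if (b$bead[i] == "GLY") "CA" else "CB", b$bead[i], b$residue[i],
        b$x[i], b$y[i], b$z[i])
  }, character(1))
  if (!is.null(np_center)) {
    lines <- c(lines, fmt(nrow(b) + 1, "NP", "NP", nrow(b) + 1,
                          np_center[1], np_center[2], np_center[3],
                          het = TRUE))
  }
  writeLines(c(lines, "END"), path)
  invisible(path)
}
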