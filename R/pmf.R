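#' Tabulated bead-surface free-energy profile
#'
#' The short-range part of the bead-particle interaction is a potential of
#' mean force tabulated against the surface separation distance (SSD)
#' `h = d - R_NP`, the distance from the particle surface to the bead centre.
#' Profiles are zero-referenced so that the mean over the last 0.1 nm before
#' the cutoff `r_c` is zero (the bulk reference required for free-energy
#' integrals); beyond `r_c` the tabulated term is identically zero and the
#' long-range core potential takes over.
#'
#' @param h Strictly increasing SSD grid in nm spanning `[h_min, r_c]`.
#' @param energy Free energy at the grid nodes. Interpreted in kT if
#'   `units = "kT"`, converted from kJ/mol (using kT at 300 K = 2.494 kJ/mol)
#'   if `units = "kJ/mol"`.
#' @param bead Bead name the profile belongs to.
#' @param facet Crystallographic facet label (`"100"`, `"110"`, `"111"`).
#' @param r_c Cutoff in nm (typically 1.0-1.2 nm).
#' @param units `"kT"` or `"kJ/mol"`.
#' @param zero_ref Apply zero-referencing (default TRUE). The constructed
#'   table must end within 0.25 kT of zero at `r_c`.
#' @return An object of class `ns_pmf` with a `data` tibble (`h`, `energy` in
#'   kT) and metadata fields.
#' @examples
#' tab <- pmf_table(seq(0.05, 1, by = 0.01),
#'                  -3 * exp(-(seq(0.05, 1, by = 0.01) - 0.3)^2 / 0.005),
#'                  bead = "ALA", facet = "110", r_c = 1.0)
#' surface_pmf_eval(tab, c(0.3, 1.5))
#' @export
pmf_table <- function(h, energy, bead = "BEAD", facet = "110", r_c = max(h),
                      units = c("kT", "kJ/mol"), zero_ref = TRUE) {
  units <- match.arg(units)
  h <- as.numeric(h); energy <- as.numeric(energy)
  if (length(h) != length(energy) || length(h) < 4) {
    stop("need matching h/energy vectors with at least 4 nodes")
  }
  if (any(!is.finite(h)) || any(!is.finite(energy))) {
    stop("PMF grid and values must be finite (no NaN)")
  }
  dd <- diff(h)
  if (any(dd <= 0)) {
    stop("PMF grid must be strictly increasing (violated after node ",
         which(dd <= 0)[1], ")")
  }
  if (!isTRUE(r_c > min(h))) stop("r_c must exceed the first grid point")
  if (max(h) < r_c - 1e-9) {
    stop("PMF grid must span up to the cutoff r_c (max h = ", max(h),
         " < r_c = ", r_c, ")")
  }
  if (units == "kJ/mol") energy <- energy / kT_kjmol(300)
  keep <- h <= r_c + 1e-12
  h <- h[keep]; energy <- energy[keep]
  if (zero_ref) {
    tail_idx <- h >= r_c - 0.1
    energy <- energy - mean(energy[tail_idx])
  }
  if (abs(energy[length(energy)]) >= 0.25) {
    stop("PMF does not decay: |value at r_c| = ",
         signif(abs(energy[length(energy)]), 3),
         " kT >= 0.25 kT after zero-referencing")
  }
  structure(
    list(data = tibble::tibble(h = h, energy = energy),
         bead = bead, facet = facet, r_c = r_c, zero_ref = zero_ref,
         .fun = stats::splinefun(h, energy, method = "monoH.FC")),
    class = "ns_pmf"
  )
}

#' @export
print.ns_pmf <- function(x, ...) {
  cat(sprintf(
    "<ns_pmf> %s on facet %s: %d nodes, h in [%.3g, %.3g] nm, min %.3g kT\n",
    x$bead, x$facet, nrow(x$data), min(x$data$h), x$r_c, min(x$data$energy)))
  invisible(x)
}

#' @export
as_tibble.ns_pmf <- function(x, ...) {
  dplyr::mutate(x$data, bead = x$bead, facet = x$facet, r_c = x$r_c)
}

# wall cap for sub-grid extrapolation (excluded volume), kT
.pmf_wall_cap <- 50

#' Evaluate a tabulated surface potential
#'
#' Monotone-shape-preserving cubic interpolation (Fritsch-Carlson) through the
#' tabulated nodes; identically zero at and beyond the cutoff `r_c`; below the
#' first grid point the profile continues as a linear repulsive wall with the
#' slope at `h_min`, capped at +50 kT (hard-core excluded volume, keeps
#' Boltzmann integrals finite).
#'
#' @param table An [pmf_table()] object.
#' @param h SSD values in nm (vectorized).
#' @return Energies in kT.
#' @export
surface_pmf_eval <- function(table, h) {
  stopifnot(inherits(table, "ns_pmf"))
  out <- numeric(length(h))
  h_min <- table$data$h[1]
  inside <- h < table$r_c & h >= h_min
  below <- h < h_min
  if (any(inside)) out[inside] <- table$.fun(h[inside])
  if (any(below)) {
    f0 <- table$data$energy[1]
    slope <- min(table$.fun(h_min, deriv = 1), 0) # wall must not attract
    out[below] <- pmin(f0 + slope * (h[below] - h_min), .pmf_wall_cap)
  }
  out
}

#' Zero-reference a surface potential
#'
#' Shifts the profile so the mean over the last 0.1 nm before `r_c` is zero.
#'
#' @param table An [pmf_table()] object.
#' @return A zero-referenced `ns_pmf`.
#' @export
zero_reference <- function(table) {
  stopifnot(inherits(table, "ns_pmf"))
  pmf_table(table$data$h, table$data$energy, bead = table$bead,
            facet = table$facet, r_c = table$r_c, zero_ref = TRUE)
}

#' Summary statistics of a surface potential
#'
#' `E_min` is the global minimum of the interpolated profile (with its SSD
#' location); the adsorption free energy is the bound-state Boltzmann weight
#' of the profile relative to a flat bulk profile over the sampled range L:
#' `dF_ads = -kT ln[(1/L) integral exp(-F(h)/kT) dh]`. A profile that is zero
#' everywhere gives `dF_ads = 0`; any purely attractive region deepens it.
#'
#' @param table A zero-referenced [pmf_table()] object.
#' @param temperature Kelvin (energies are already in kT; temperature is
#'   carried for unit conversions in reports).
#' @return A one-row tibble: `dF_ads` (kT), `E_min` (kT), `h_min_location`
#'   (nm), `binding` (logical, TRUE if the profile has a negative minimum).
#' @export
pmf_summary <- function(table, temperature = 300) {
  stopifnot(inherits(table, "ns_pmf"))
  if (!isTRUE(table$zero_ref)) {
    stop("pmf_summary requires a zero-referenced table (see zero_reference())")
  }
  h_lo <- table$data$h[1]
  step <- max(min(min(diff(table$data$h)) / 2, 1e-3), 1e-5)
  hh <- seq(h_lo, table$r_c, by = step)
  ff <- surface_pmf_eval(table, hh)
  i_min <- which.min(ff)
  # local refinement of the minimum between neighbouring fine-grid nodes
  lo <- max(h_lo, hh[i_min] - step)
  hi <- min(table$r_c, hh[i_min] + step)
  opt <- stats::optimize(function(x) surface_pmf_eval(table, x), c(lo, hi))
  E_min <- min(opt$objective, ff[i_min])
  h_at <- if (opt$objective <= ff[i_min]) opt$minimum else hh[i_min]
  L <- table$r_c - h_lo
  w <- exp(-pmin(ff, .pmf_wall_cap))
  Z <- sum((w[-1] + w[-length(w)]) / 2 * diff(hh))
  tibble::tibble(
    dF_ads = -log(Z / L),
    E_min = E_min,
    h_min_location = h_at,
    binding = E_min < 0
  )
}

#' Read / write a surface-potential table file
#'
#' Whitespace-delimited two-column text (`h_nm`, `energy`) with `#`-prefixed
#' header lines `bead`, `facet`, `units` (`kT` or `kJ/mol`) and `r_c`. Values
#' in kJ/mol are converted to kT (at 300 K) on load; the write/read pair
#' round-trips losslessly to 1e-9.
#'
#' @param path File path.
#' @return `read_pmf_table()` returns an [pmf_table()]; `write_pmf_table()`
#'   returns `path` invisibly.
#' @export
read_pmf_table <- function(path) {
  if (!file.exists(path)) stop("no such PMF table file: ", path)
  lines <- readLines(path)
  hdr_lines <- grep("^\\s*#", lines, value = TRUE)
  hdr <- list()
  for (l in hdr_lines) {
    m <- regmatches(l, regexec("^\\s*#\\s*([A-Za-z_]+)\\s*:\\s*(\\S+)", l))[[1]]
    if (length(m) == 3) hdr[[m[2]]] <- m[3]
  }
  need <- c("bead", "facet", "units", "r_c")
  missing <- setdiff(need, names(hdr))
  if (length(missing) > 0) {
    stop("PMF table ", path, " is missing header key(s): ",
         paste(missing, collapse = ", "))
  }
  body_idx <- which(!grepl("^\\s*#", lines) & nzchar(trimws(lines)))
  if (length(body_idx) == 0) stop("PMF table ", path, " has no data rows")
  fields <- strsplit(trimws(lines[body_idx]), "\\s+")
  bad <- which(lengths(fields) != 2)
  if (length(bad) > 0) {
    stop("malformed PMF row at line ", body_idx[bad[1]], " of ", path)
  }
  vals <- suppressWarnings(
    matrix(as.numeric(unlist(fields)), ncol = 2, byrow = TRUE))
  if (any(is.na(vals))) {
    bad <- body_idx[which(rowSums(is.na(vals)) > 0)[1]]
    stop("non-numeric or NaN PMF value at line ", bad, " of ", path)
  }
  dd <- diff(vals[, 1])
  if (any(dd <= 0)) {
    stop("non-monotone PMF grid at line ", body_idx[which(dd <= 0)[1] + 1],
         " of ", path)
  }
  pmf_table(vals[, 1], vals[, 2], bead = hdr$bead, facet = hdr$facet,
            r_c = as.numeric(hdr$r_c), units = hdr$units)
}

#' @rdname read_pmf_table
#' @param table An [pmf_table()] object.
#' @export
write_pmf_table <- function(table, path) {
  stopifnot(inherits(table, "ns_pmf"))
  hdr <- c(
    paste0("# bead: ", table$bead),
    paste0("# facet: ", table$facet),
    "# units: kT",
    paste0("# r_c: ", format(table$r_c, digits = 12)),
    "# columns: h_nm energy_kT"
  )
  rows <- sprintf("%.10g %.10g", table$data$h, table$data$energy)
  writeLines(c(hdr, rows), path)
  invisible(path)
}

#' Library of surface-potential tables
#'
#' A keyed collection of [pmf_table()] objects, looked up by bead name and
#' facet. `read_pmf_library()` loads every `*.pmf` file in a directory.
#'
#' @param tables A list of `ns_pmf` objects.
#' @return An object of class `ns_pmf_library`.
#' @export
pmf_library <- function(tables) {
  stopifnot(all(purrr::map_lgl(tables, inherits, "ns_pmf")))
  names(tables) <- purrr::map_chr(tables, ~ paste(.x$bead, .x$facet, sep = ":"))
  structure(tables, class = "ns_pmf_library")
}

#' @rdname pmf_library
#' @param dir Directory containing `*.pmf` files.
#' @export
read_pmf_library <- function(dir) {
  files <- list.files(dir, pattern = "\\.pmf$", full.names = TRUE)
  if (length(files) == 0) stop("no .pmf files in ", dir)
  pmf_library(purrr::map(files, read_pmf_table))
}

#' @rdname pmf_library
#' @param lib An `ns_pmf_library`.
#' @param out_dir Output directory (created if needed).
#' @export
write_pmf_library <- function(lib, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  for (tab in lib) {
    write_pmf_table(tab, file.path(out_dir,
                                   paste0(tab$bead, "_", tab$facet, ".pmf")))
  }
  invisible(out_dir)
}

#' Look up the table for a bead/facet pair
#'
#' @param lib An `ns_pmf_library`.
#' @param bead Bead (PMF) name.
#' @param facet Facet label.
#' @return The matching `ns_pmf`; a missing pair is an error naming it.
#' @export
pmf_lookup <- function(lib, bead, facet) {
  key <- paste(bead, facet, sep = ":")
  tab <- lib[[key]]
  if (is.null(tab)) {
    stop("no surface potential tabulated for bead/facet pair ", key)
  }
  tab
}
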