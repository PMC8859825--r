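# Deterministic synthetic fixtures: surface-potential profiles emulating the
# shape of metadynamics PMFs at a metal-water interface, and toy proteins for
# exercising the rigid-body engine.

with_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  force(code)
}

#' Specification for a synthetic surface potential
#'
#' The generated profiles emulate the characteristic shape of bead-metal
#' adsorption free energies in water: a steep repulsive wall at contact, an
#' adsorption minimum between the two structured water adlayers (defaults
#' 0.2 nm), a second, shallower minimum at the second hydration shell
#' (0.47 nm) separated by a small barrier, and decay to zero at the cutoff.
#'
#' @param depths Well depths in kT (negative), one per well.
#' @param locations Well positions in nm.
#' @param widths Gaussian well widths (sigma, nm).
#' @param barrier_height Barrier height in kT between the wells.
#' @param barrier_location Barrier position in nm.
#' @param r_c Cutoff in nm.
#' @param h_min First grid point in nm.
#' @param step Grid spacing in nm.
#' @param wall_height,wall_decay Contact-wall amplitude (kT) and decay length
#'   (nm).
#' @param noise Amplitude (kT) of smooth seeded roughness; 0 for a clean
#'   profile.
#' @param seed Integer seed controlling the roughness.
#' @param bead,facet Labels for the resulting table.
#' @return A list of class `ns_pmf_spec`.
#' @export
synthetic_pmf_spec <- function(depths = c(-5, -2.5),
                               locations = c(0.2, 0.47),
                               widths = rep(0.04, length(depths)),
                               barrier_height = if (length(locations) > 1) 0.5 else 0,
                               barrier_location = mean(locations),
                               r_c = 1.0, h_min = 0.05, step = 0.01,
                               wall_height = 40, wall_decay = 0.02,
                               noise = 0, seed = 1,
                               bead = "ALA", facet = "110") {
  stopifnot(length(depths) == length(locations),
            length(widths) == length(depths),
            all(locations > h_min), all(locations < r_c),
            r_c > h_min, step > 0, noise >= 0)
  structure(
    list(depths = depths, locations = locations, widths = widths,
         barrier_height = barrier_height, barrier_location = barrier_location,
         r_c = r_c, h_min = h_min, step = step, wall_height = wall_height,
         wall_decay = wall_decay, noise = noise, seed = seed,
         bead = bead, facet = facet),
    class = "ns_pmf_spec"
  )
}

#' Generate a synthetic surface potential
#'
#' Deterministic for a fixed spec (including its seed). The generated table
#' satisfies all tabulated-profile invariants: strictly increasing grid,
#' repulsive wall below the first minimum, smooth decay to |value| < 0.25 kT
#' at the cutoff.
#'
#' @param spec A [synthetic_pmf_spec()].
#' @return An [pmf_table()] object.
#' @examples
#' tab <- synth_pmf(synthetic_pmf_spec(depths = -6, locations = 0.3,
#'                                     widths = 0.05))
#' pmf_summary(tab)
#' @export
synth_pmf <- function(spec = synthetic_pmf_spec()) {
  stopifnot(inherits(spec, "ns_pmf_spec"))
  h <- seq(spec$h_min, spec$r_c, by = spec$step)
  if (h[length(h)] < spec$r_c) h <- c(h, spec$r_c)
  wall <- spec$wall_height * exp(-(h - spec$h_min) / spec$wall_decay)
  wells <- rowSums(vapply(seq_along(spec$depths), function(k) {
    spec$depths[k] * exp(-(h - spec$locations[k])^2 / (2 * spec$widths[k]^2))
  }, numeric(length(h))))
  barrier <- spec$barrier_height *
    exp(-(h - spec$barrier_location)^2 / (2 * 0.03^2))
  rough <- 0
  if (spec$noise > 0) {
    rough <- with_seed(spec$seed, {
      centres <- stats::runif(6, spec$h_min + 0.05, spec$r_c - 0.25)
      amps <- spec$noise * stats::runif(6, -1, 1)
      rowSums(vapply(seq_along(centres), function(k) {
        amps[k] * exp(-(h - centres[k])^2 / (2 * 0.05^2))
      }, numeric(length(h))))
    })
  }
  # cosine switch taking the structured part smoothly to zero at the cutoff
  sw <- ifelse(h < spec$r_c - 0.15, 1,
               0.5 * (1 + cos(pi * (h - (spec$r_c - 0.15)) / 0.15)))
  energy <- wall + sw * (wells + barrier + rough)
  pmf_table(h, energy, bead = spec$bead, facet = spec$facet, r_c = spec$r_c)
}

#' Generate a synthetic surface-potential library
#'
#' One table per (bead, facet) pair with seeded per-pair variation of the well
#' depths around the template spec, mimicking a full parametrization set.
#'
#' @param beads Character vector of bead (PMF) names.
#' @param facets Character vector of facet labels.
#' @param seed Integer seed.
#' @param template A [synthetic_pmf_spec()] providing the common shape.
#' @return An [pmf_library()].
#' @export
synth_pmf_library <- function(beads, facets = c("100", "110", "111"),
                              seed = 1,
                              template = synthetic_pmf_spec()) {
  combos <- expand.grid(bead = beads, facet = facets,
                        stringsAsFactors = FALSE)
  scales <- with_seed(seed, stats::runif(nrow(combos), 0.5, 1.5))
  tabs <- purrr::map(seq_len(nrow(combos)), function(i) {
    sp <- template
    sp$depths <- sp$depths * scales[i]
    sp$bead <- combos$bead[i]
    sp$facet <- combos$facet[i]
    sp$seed <- seed + i
    synth_pmf(sp)
  })
  pmf_library(tabs)
}

#' Deterministic toy protein
#'
#' Builds small bead arrangements for engine tests: a straight `line` of beads
#' along x, a two-bead `dumbbell` along z, or a seeded `random-coil` walk.
#' Returns both the in-memory protein and its PDB text, which re-imports via
#' [build_cg_protein()] to the same positions within PDB coordinate precision
#' (1e-3 nm). Bead names must exist in the registry.
#'
#' @param n_beads Number of beads (>= 1; exactly 2 for a dumbbell).
#' @param geometry `"line"`, `"dumbbell"` or `"random-coil"`.
#' @param bead_names Residue names, recycled to `n_beads`.
#' @param spacing Bead spacing in nm (default 0.4; 1.0 for dumbbells).
#' @param seed Seed for the random coil.
#' @param registry Bead registry.
#' @return A list with `protein` (an `ns_protein`) and `pdb_text` (character
#'   lines).
#' @export
toy_protein <- function(n_beads = 1,
                        geometry = c("line", "dumbbell", "random-coil"),
                        bead_names = "ALA",
                        spacing = NULL, seed = 1,
                        registry = default_bead_registry()) {
  geometry <- match.arg(geometry)
  stopifnot(n_beads >= 1)
  if (geometry == "dumbbell" && n_beads != 2) {
    stop("a dumbbell has exactly 2 beads")
  }
  spacing <- spacing %||% if (geometry == "dumbbell") 1.0 else 0.4
  bead_names <- rep_len(bead_names, n_beads)
  params <- registry_lookup(registry, bead_names)
  xyz <- switch(geometry,
    line = cbind((seq_len(n_beads) - (n_beads + 1) / 2) * spacing, 0, 0),
    dumbbell = cbind(0, 0, c(-spacing / 2, spacing / 2)),
    `random-coil` = with_seed(seed, {
      steps <- matrix(stats::rnorm(3 * n_beads), ncol = 3)
      steps <- steps / sqrt(rowSums(steps^2)) * spacing
      steps[1, ] <- 0
      pos <- apply(steps, 2, cumsum)
      if (n_beads == 1) pos <- matrix(pos, ncol = 3)
      sweep(pos, 2, colMeans(pos))
    })
  )
  if (n_beads == 1) xyz <- matrix(xyz, ncol = 3)
  beads <- tibble::tibble(
    residue = seq_len(n_beads), resid = params$name, bead = params$name,
    pmf_name = params$pmf_name, charge = params$charge,
    radius = params$radius, material_id = params$material_id,
    x = round(xyz[, 1], 4), y = round(xyz[, 2], 4), z = round(xyz[, 3], 4)
  )
  protein <- cg_protein(beads, source_id = paste0("toy_", geometry))
  path <- tempfile(fileext = ".pdb")
  on.exit(unlink(path), add = TRUE)
  write_cg_pdb(protein, path)
  list(protein = protein, pdb_text = readLines(path))
}
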