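# Run configuration and deterministic report writing.

#' Read a run configuration file
#'
#' Structured key-value text (YAML; JSON is also accepted) describing a batch
#' adsorption run: protein PDB paths, particle specification (shape, radius,
#' zeta potential, facets and weights), medium (salt concentration, dielectric,
#' temperature), the PMF table directory, grid resolution in degrees, output
#' directory and random seed. All referenced paths are checked at load time;
#' defaults mirror physiological conditions (0.15 M monovalent salt, 300 K)
#' and equal facet weights.
#'
#' @param path Path to a YAML or JSON configuration file.
#' @return A list of class `ns_config` with elements `proteins`, `np`,
#'   `medium`, `pmf_dir`, `grid_deg`, `out_dir`, `seed`.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) stop("no such config file: ", path)
  raw <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  proteins <- as.character(raw$proteins %||% character())
  missing <- proteins[!file.exists(proteins)]
  if (length(missing) > 0) {
    stop("protein file(s) not found: ", paste(missing, collapse = ", "))
  }
  pmf_dir <- raw$pmf_dir %||% stop("config must name a pmf_dir")
  if (!dir.exists(pmf_dir)) stop("pmf_dir not found: ", pmf_dir)
  npc <- raw$np %||% list()
  np <- nanoparticle(
    shape = npc$shape %||% "sphere",
    radius = npc$radius_nm %||% 20,
    zeta_mV = npc$zeta_mV %||% 0,
    facets = as.character(npc$facets %||% c("100", "110", "111")),
    facet_weights = npc$facet_weights %||% NULL,
    material_id = npc$material_id %||% "silver"
  )
  mc <- raw$medium %||% list()
  med <- medium(
    species = saline_species(mc$ionic_strength_M %||% 0.15),
    dielectric = mc$dielectric %||% 78.4,
    temperature = mc$temperature_K %||% 300
  )
  structure(
    list(proteins = proteins, np = np, medium = med, pmf_dir = pmf_dir,
         grid_deg = raw$grid_deg %||% 5,
         out_dir = raw$out_dir %||% "nanosorb_out",
         seed = raw$seed %||% 1),
    class = "ns_config"
  )
}

#' Write a deterministic report of adsorption results
#'
#' Writes, under `out_dir`: one heatmap CSV per protein and facet (rows theta
#' in degrees, columns phi), a ranking TSV over all proteins (ascending
#' E_ads^B), one pose PDB and contact TSV per protein, a run manifest
#' (settings and package version, JSON), and a structured one-line-per-result
#' log. Identical inputs produce byte-identical files.
#'
#' @param results A list of `ns_adsorption` objects (see [adsorb_protein()]).
#' @param out_dir Output directory, created if needed.
#' @param manifest Optional named list of run settings recorded in the
#'   manifest.
#' @return Invisibly, a character vector of the files written.
#' @export
report <- function(results, out_dir, manifest = list()) {
  ok <- dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  if (!dir.exists(out_dir)) stop("cannot create output directory: ", out_dir)
  written <- character()
  log_lines <- character()
  for (res in results) {
    stopifnot(inherits(res, "ns_adsorption"))
    id <- gsub("[^A-Za-z0-9_.-]", "_", res$protein_id)
    for (facet in names(res$maps)) {
      m <- res$maps[[facet]]
      wide <- tidyr::pivot_wider(
        tibble::as_tibble(m)[, c("theta", "phi", "E")],
        names_from = "phi", values_from = "E")
      wide$theta <- round(wide$theta * 180 / pi, 6)
      names(wide) <- c("theta_deg",
                       round(as.numeric(names(wide)[-1]) * 180 / pi, 6))
      f <- file.path(out_dir, sprintf("heatmap_%s_facet%s.csv", id, facet))
      utils::write.csv(wide, f, row.names = FALSE)
      written <- c(written, f)
    }
    f_pose <- file.path(out_dir, sprintf("pose_%s.pdb", id))
    np_center <- if (res$np$shape == "sphere") c(0, 0, 0) else c(0, 0, -1)
    write_cg_pdb(res$best$protein, f_pose, np_center = np_center)
    f_contact <- file.path(out_dir, sprintf("contacts_%s.tsv", id))
    utils::write.table(res$best$contacts, f_contact, sep = "\t",
                       row.names = FALSE, quote = FALSE)
    written <- c(written, f_pose, f_contact)
    for (facet in names(res$maps)) {
      pf <- res$per_facet[res$per_facet$facet == facet, ]
      log_lines <- c(log_lines, sprintf(
        "protein=%s facet=%s E_ads_A_kT=%.6f E_ads_B_kT=%.6f best_theta=%.6f best_phi=%.6f best_z_nm=%.6f",
        id, facet, pf$E_ads_A, pf$E_ads_B,
        res$best$state$theta, res$best$state$phi, res$best$state$z))
    }
  }
  ranking <- if (length(results) > 0) {
    rank_proteins(stats::setNames(
      purrr::map_dbl(results, "E_ads_B"),
      purrr::map_chr(results, "protein_id")))
  } else {
    tibble::tibble(rank = integer(), id = character(), energy = numeric(),
                   tied = logical())
  }
  f_rank <- file.path(out_dir, "ranking.tsv")
  utils::write.table(ranking, f_rank, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  manifest_full <- c(manifest, list(
    package = "nanosorb",
    version = as.character(utils::packageVersion("nanosorb")),
    n_proteins = length(results)
  ))
  f_manifest <- file.path(out_dir, "manifest.json")
  jsonlite::write_json(manifest_full, f_manifest, auto_unbox = TRUE,
                       pretty = TRUE, digits = NA)
  f_log <- file.path(out_dir, "run.log")
  writeLines(log_lines, f_log)
  invisible(c(written, f_rank, f_manifest, f_log))
}
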