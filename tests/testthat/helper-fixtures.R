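# Shared fixtures: built in code, deterministic.

# flat zero surface potential (all terms vanish)
zero_pmf <- function(bead = "ALA", facet = "110", r_c = 1.0) {
  h <- seq(0.05, r_c, by = 0.05)
  pmf_table(h, rep(0, length(h)), bead = bead, facet = facet, r_c = r_c)
}

# single-well table per bead name, depths named by bead
well_lib <- function(depths, facet = "110", location = 0.25, width = 0.05) {
  pmf_library(purrr::imap(depths, function(d, nm) {
    synth_pmf(synthetic_pmf_spec(depths = d, locations = location,
                                 widths = width, bead = nm, facet = facet))
  }))
}

# hand-built single-ALA PDB: side-chain centroid is the lone CB atom
ala_pdb_lines <- function(cb = c(1.0, 2.0, 3.0)) {
  fmt <- function(serial, name, x, y, z) {
    sprintf("%-6s%5d %-4s %-4s%1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f",
            "ATOM", serial, name, "ALA", "A", 1, x, y, z, 1, 0)
  }
  c(fmt(1, "N", 0, 0, 0), fmt(2, "CA", 1.5, 0, 0), fmt(3, "C", 2.2, 1.2, 0),
    fmt(4, "O", 3.4, 1.3, 0), fmt(5, "CB", cb[1], cb[2], cb[3]), "END")
}

# independently coded rotation oracle (distinct construction from the
# package's rotation_matrix): axis-angle composition via quaternions
oracle_rotate <- function(xyz, com, theta, phi) {
  quat_rot <- function(v, axis, ang) {
    axis <- axis / sqrt(sum(axis^2))
    v * cos(ang) + pracma::cross(axis, v) * sin(ang) +
      axis * sum(axis * v) * (1 - cos(ang))
  }
  t(apply(xyz, 1, function(p) {
    v <- p - com
    v <- quat_rot(v, c(0, 1, 0), theta)
    v <- quat_rot(v, c(0, 0, 1), phi)
    v + com
  }))
}

# random orientation-map-like tibble for averaging properties
random_map <- function(n = 40, seed = 1) {
  withr::with_seed(seed, {
    w <- stats::runif(n)
    tibble::tibble(theta = stats::runif(n, 0, pi),
                   phi = stats::runif(n, 0, 2 * pi),
                   weight = w / sum(w),
                   E = stats::rnorm(n, -3, 4))
  })
}
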