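# Interfacial hydrophobicity descriptors and validation statistics.

# Block-averaged standard error of the mean for a (possibly autocorrelated)
# series: block sizes double until the error estimate plateaus (relative
# change < 5% across two doublings) or blocks run out.
block_average_error <- function(x) {
  n <- length(x)
  sizes <- 2^(0:floor(log2(n / 4)))
  errs <- vapply(sizes, function(bs) {
    nb <- floor(n / bs)
    means <- colMeans(matrix(x[seq_len(nb * bs)], nrow = bs))
    stats::sd(means) / sqrt(nb)
  }, numeric(1))
  if (length(errs) >= 3) {
    for (k in 3:length(errs)) {
      r1 <- abs(errs[k] - errs[k - 1]) / max(errs[k], 1e-12)
      r2 <- abs(errs[k - 1] - errs[k - 2]) / max(errs[k - 1], 1e-12)
      if (r1 < 0.05 && r2 < 0.05) return(errs[k])
    }
  }
  errs[length(errs)]
}

#' Immersion enthalpy of a slab in a liquid
#'
#' The enthalpy of wetting per interfacial area, from the mean enthalpies of
#' three simulated systems: the solvated slab, the dry slab, and a box of the
#' same amount of pure liquid:
#' `dH_imm = (H_slab_liquid - H_slab - H_liquid) / A`.
#' Each input may be a single mean (kJ/mol) or an energy time series, in which
#' case the mean and a block-averaged standard error are computed
#' (block-doubling until the error estimate plateaus).
#'
#' @param H_slab_liquid,H_slab,H_liquid Mean enthalpies in kJ/mol, or numeric
#'   time series (length >= 100) thereof.
#' @param area Total interfacial area A in nm^2 (> 0; count both faces of a
#'   periodic slab).
#' @return A one-row tibble: `H_slab_liquid`, `H_slab`, `H_liquid`, `area`,
#'   `dH_imm` (kJ/(mol nm^2)), `error` (kJ/(mol nm^2), NA for scalar input).
#' @examples
#' immersion_enthalpy(-1000, -300, -650, area = 10) # -5 kJ/(mol nm^2)
#' @export
immersion_enthalpy <- function(H_slab_liquid, H_slab, H_liquid, area) {
  if (!isTRUE(area > 0)) stop("interfacial area must be > 0 nm^2")
  summarise1 <- function(x, nm) {
    if (length(x) == 1) return(list(mean = x, err = NA_real_))
    if (length(x) < 100) {
      stop(nm, ": an enthalpy time series needs >= 100 samples")
    }
    list(mean = mean(x), err = block_average_error(x))
  }
  sl <- summarise1(H_slab_liquid, "H_slab_liquid")
  s <- summarise1(H_slab, "H_slab")
  l <- summarise1(H_liquid, "H_liquid")
  err <- if (all(is.na(c(sl$err, s$err, l$err)))) NA_real_ else {
    sqrt(sum(c(sl$err, s$err, l$err)^2, na.rm = TRUE)) / area
  }
  tibble::tibble(
    H_slab_liquid = sl$mean, H_slab = s$mean, H_liquid = l$mean,
    area = area,
    dH_imm = (sl$mean - s$mean - l$mean) / area,
    error = err
  )
}

#' Nanomaterial hydrophobicity descriptor log P
#'
#' Relative lipophilicity of a crystalline nanomaterial from the difference of
#' its immersion enthalpies per interfacial area in water and in n-octanol:
#' `logP_NM = (dH_imm_water - dH_imm_octanol) / (RT ln 10)` per nm^2 of
#' interface, with T = 298.15 K by default. Positive values indicate affinity
#' for lipophilic environments (octanol wets the slab more exothermically);
#' negative values indicate a hydrophilic surface. The descriptor is
#' antisymmetric under swapping the two phases.
#'
#' @param dH_imm_water,dH_imm_octanol Immersion enthalpies in kJ/(mol nm^2)
#'   (vectorized).
#' @param temperature Kelvin.
#' @return Dimensionless log P values.
#' @examples
#' log_p_nm(-206.7, -289.0)  # Ag(110): about 14.4
#' @export
log_p_nm <- function(dH_imm_water, dH_imm_octanol, temperature = 298.15) {
  stopifnot(all(is.finite(dH_imm_water)), all(is.finite(dH_imm_octanol)))
  RT <- .const$Rgas * temperature / 1000 # kJ/mol
  (dH_imm_water - dH_imm_octanol) / (RT * log(10))
}

#' Pearson correlation with t-transform p-value
#'
#' Standard product-moment correlation between two equal-length numeric
#' vectors plus the two-sided p-value from the t transform
#' `t = r sqrt((n-2)/(1-r^2))`.
#'
#' @param x,y Numeric vectors, length >= 3, each with nonzero variance.
#' @return A one-row tibble: `r`, `p_value`, `n`.
#' @examples
#' pearson_r(1:5, 2 * (1:5) + 1)
#' @export
pearson_r <- function(x, y) {
  if (length(x) != length(y)) stop("x and y must have equal length")
  if (length(x) < 3) stop("need at least 3 observations")
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    stop("zero variance in x or y")
  }
  ct <- stats::cor.test(x, y, method = "pearson")
  tibble::tibble(r = unname(ct$estimate), p_value = ct$p.value,
                 n = length(x))
}

#' Rank proteins by binding affinity
#'
#' Orders proteins ascending by adsorption energy (most negative = strongest
#' binder = rank 1); exact ties are broken lexicographically by id and
#' flagged. When a reference ranking is supplied, the number of positions in
#' agreement and the Kendall tau between the two orders are attached as
#' attributes `agreement` and `kendall_tau`.
#'
#' @param energies Named numeric vector (names = protein ids) or a two-column
#'   data frame (`id`, `energy`).
#' @param reference Optional character vector: ids in reference rank order.
#' @return A tibble with `rank`, `id`, `energy`, `tied`.
#' @examples
#' rank_proteins(c(B = -2, A = -5, C = -2))
#' @export
rank_proteins <- function(energies, reference = NULL) {
  if (is.data.frame(energies)) {
    ids <- as.character(energies[[1]])
    en <- as.numeric(energies[[2]])
  } else {
    ids <- names(energies)
    en <- as.numeric(energies)
  }
  if (length(en) < 1) stop("need at least one protein")
  if (is.null(ids)) stop("energies must carry protein ids")
  ord <- order(en, ids)
  out <- tibble::tibble(
    rank = seq_along(ord), id = ids[ord], energy = en[ord],
    tied = duplicated(en[ord]) | duplicated(en[ord], fromLast = TRUE)
  )
  if (!is.null(reference)) {
    common <- intersect(out$id, reference)
    ref_pos <- match(common, reference)
    got_pos <- match(common, out$id)
    attr(out, "agreement") <- sum(ref_pos == got_pos)
    attr(out, "kendall_tau") <-
      unname(stats::cor(ref_pos, got_pos, method = "kendall"))
  }
  out
}
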