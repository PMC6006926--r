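#' Protein carbonyl content from DNPH-assay absorbance
#'
#' Beer-Lambert conversion of absorbance at 345 nm to nanomoles of
#' carbonyl groups per milligram of protein. With the millimolar
#' extinction coefficient of aliphatic hydrazones (22 mM^-1 cm^-1):
#' concentration (mM) = A345 / (22 * path_cm); since 1 mM is 1 nmol/ul,
#' nmol carbonyl = concentration * volume_ul, and the result is divided by
#' the protein mass. Used as the per-queen biological-age proxy.
#'
#' @param A345 absorbance at 345 nm (>= 0).
#' @param path_cm optical path length in cm (default 1).
#' @param volume_ul resuspension volume in microlitres (default 100, the
#'   guanidine resuspension volume of the assay).
#' @param protein_mg protein mass in the reaction, mg (> 0).
#' @param epsilon_mM millimolar extinction coefficient (default 22).
#' @return nmol carbonyl per mg protein; vectorized over all arguments.
#' @export
carbonyl_per_mg <- function(A345, path_cm = 1, volume_ul = 100, protein_mg,
                            epsilon_mM = 22) {
  if (any(A345 < 0)) stop("A345 must be non-negative")
  if (any(path_cm <= 0) || any(volume_ul <= 0) || any(epsilon_mM <= 0))
    stop("path_cm, volume_ul and epsilon_mM must be positive")
  if (any(!is.finite(protein_mg)) || any(protein_mg <= 0))
    stop("protein_mg must be positive")
  mM <- A345 / (epsilon_mM * path_cm)
  nmol <- mM * volume_ul
  nmol / protein_mg
}

#' Log-transform carbonyl values
#'
#' Natural log by default. Zeros are offset to half the smallest positive
#' value (with a warning) so the transform is defined; an all-zero vector
#' is an error.
#'
#' @param x non-negative carbonyl values (nmol/mg).
#' @param base log base (default `exp(1)`).
#' @return transformed vector.
#' @export
log_carbonyl <- function(x, base = exp(1)) {
  if (any(x < 0)) stop("carbonyl values must be non-negative")
  if (all(x == 0)) stop("all carbonyl values are zero; log undefined")
  if (any(x == 0)) {
    offset <- min(x[x > 0]) / 2
    warning(sum(x == 0), " zero value(s) offset to ", signif(offset, 3))
    x[x == 0] <- offset
  }
  log(x, base = base)
}
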