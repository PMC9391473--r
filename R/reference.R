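#' Published reference repeatability components
#'
#' The per-measurement statistical components of the 10-volunteer,
#' 3-scan 7 T test-retest study this package models, as printed: pooled
#' mean and SD, inter- and intra-subject variance, CV (percent) and ICC
#' for the mean and SD of normalized PD, T1, T2 and normalized sodium
#' density in GM, WM and CSF. The (PD, CSF, mean) row is the defined
#' normalization constant 1 and carries no variability statistics.
#'
#' @return Data.frame with columns `parameter`, `tissue`, `statistic`,
#'   `mean_all`, `sd_all`, `inter_var`, `intra_var`, `cv_percent`, `icc`.
#' @export
reference_components <- function() {
  path <- system.file("extdata", "reference_components.csv",
                      package = "mrfrepeat", mustWork = TRUE)
  read.csv(path, stringsAsFactors = FALSE)
}

#' Verify printed ICCs against their printed variance components
#'
#' Recomputes `icc(inter_var, intra_var)` for every row that prints both
#' variance components, rounds to 2 decimals and compares with the
#' printed ICC. A tolerance of 0.01 absorbs the rounding of the printed
#' components themselves.
#'
#' @param components Data.frame in the [reference_components()] schema
#'   (that table by default).
#' @param tolerance Maximum allowed |recomputed - printed| after rounding.
#' @return Data.frame with `icc_recomputed`, `abs_diff`, `pass` columns
#'   appended; rows without components carry `NA`.
#' @export
check_table_components <- function(components = reference_components(),
                                   tolerance = 0.01) {
  need <- c("parameter", "tissue", "statistic", "inter_var", "intra_var", "icc")
  if (!all(need %in% names(components)))
    stop("malformed components table; need columns: ", paste(need, collapse = ", "))
  out <- components
  has <- !is.na(out$inter_var) & !is.na(out$intra_var)
  out$icc_recomputed <- NA_real_
  out$icc_recomputed[has] <- mapply(icc, out$inter_var[has], out$intra_var[has])
  out$abs_diff <- abs(round(out$icc_recomputed, 2) - out$icc)
  out$pass <- ifelse(has, out$abs_diff <= tolerance + 1e-12, NA)
  out
}
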