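#' Binarize tissue probability maps into non-overlapping masks
#'
#' Optionally renormalizes the GM/WM/CSF probabilities to sum to one where
#' their sum is positive, then assigns a voxel to a tissue iff that
#' tissue's probability is at least `threshold`. With any threshold above
#' 0.5 the resulting masks are structurally pairwise disjoint (two
#' probabilities cannot both reach it); voxels reaching no threshold are
#' excluded from every mask, which suppresses partial-volume voxels.
#'
#' @param prob_maps List with arrays `gm`, `wm`, `csf` of probabilities in
#'   \[0, 1\].
#' @param threshold Binarization threshold in (0.5, 1\]; default 0.9.
#' @param renormalize Divide by the three-tissue sum before thresholding
#'   wherever that sum is at least 0.5 (default `TRUE`); voxels whose
#'   tissue probabilities sum to less than 0.5 (skull, background, eyes)
#'   are zeroed rather than renormalized.
#' @return List of logical arrays `gm`, `wm`, `csf`.
#' @export
binarize_masks <- function(prob_maps, threshold = 0.9, renormalize = TRUE) {
  stopifnot(all(c("gm", "wm", "csf") %in% names(prob_maps)))
  if (!(threshold > 0.5 && threshold <= 1))
    stop("threshold must lie in (0.5, 1]: disjointness is otherwise not guaranteed")
  g <- prob_maps$gm; w <- prob_maps$wm; c3 <- prob_maps$csf
  rng <- range(g, w, c3)
  if (rng[1] < -1e-9 || rng[2] > 1 + 1e-9) stop("probabilities must lie in [0, 1]")
  if (renormalize) {
    # renormalize only where the three tissues carry most of the voxel:
    # dividing near-zero sums would promote exterior voxels into a mask
    s <- g + w + c3
    pos <- s >= 0.5
    g[pos] <- g[pos] / s[pos]; w[pos] <- w[pos] / s[pos]; c3[pos] <- c3[pos] / s[pos]
    g[!pos] <- 0; w[!pos] <- 0; c3[!pos] <- 0
  }
  list(gm = g >= threshold, wm = w >= threshold, csf = c3 >= threshold)
}

#' Normalize a proton-density map by its CSF mean
#'
#' Divides every voxel by the mean intensity over the binarized CSF mask,
#' so the normalized CSF mean is exactly 1 (the defined reference value).
#' Scale-invariant and idempotent.
#'
#' @param pd_map Numeric array.
#' @param csf_mask Logical array of the same geometry, non-empty.
#' @return Normalized map.
#' @export
normalize_pd <- function(pd_map, csf_mask) {
  stopifnot(all(dim(pd_map) == dim(csf_mask)))
  if (!any(csf_mask)) stop("empty CSF mask")
  m <- mean(pd_map[csf_mask])
  if (!is.finite(m) || m <= 0) stop("non-positive CSF mean; cannot normalize")
  pd_map / m
}

#' Normalize a sodium image by the eye (vitreous humor) mean
#'
#' The eyes carry the maximum sodium signal in the volume, making their
#' mean a stable internal reference; after division the eye-ROI mean is
#' exactly 1. Scale-invariant and idempotent.
#'
#' @param na_map Numeric array on the sodium grid.
#' @param eye_roi Logical array of the same geometry, non-empty.
#' @return Normalized sodium image.
#' @export
normalize_na <- function(na_map, eye_roi) {
  stopifnot(all(dim(na_map) == dim(eye_roi)))
  if (!any(eye_roi)) stop("empty eye ROI")
  m <- mean(na_map[eye_roi])
  if (!is.finite(m) || m <= 0) stop("non-positive eye mean; cannot normalize")
  na_map / m
}

#' Resample a proton-grid mask onto the sodium grid
#'
#' Nearest-neighbour label resampling: each coarse sodium voxel takes the
#' value of the fine proton voxel closest to its center. Labels are
#' preserved, so pairwise-disjoint masks stay disjoint.
#'
#' @param mask Logical array on the proton grid.
#' @param na_shape Sodium grid dimensions (3 integers), or a
#'   [phantom_spec()] whose `na_shape` is used.
#' @return Logical array on the sodium grid.
#' @export
resample_mask_to_na_grid <- function(mask, na_shape) {
  if (inherits(na_shape, "phantom_spec")) na_shape <- na_shape$na_shape
  stopifnot(length(dim(mask)) == 3, length(na_shape) == 3)
  nmap <- na_index_map(dim(mask), as.integer(na_shape))
  array(mask[nmap$ix, nmap$iy, nmap$iz], as.integer(na_shape))
}
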