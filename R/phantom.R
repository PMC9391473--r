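#' Digital head phantom specification
#'
#' Geometry and sampling description of the synthetic head: concentric
#' ellipsoidal white-matter core, grey-matter shell and CSF outer shell,
#' two ellipsoidal ventricles (CSF) and two eyes (vitreous humor) anterior
#' to the head. The sodium image lives on a grid whose in-plane resolution
#' is coarser than the proton grid by `na_inplane_factor` (default 1.9,
#' matching the simultaneous acquisition's proton/sodium resolution ratio);
#' slices are shared.
#'
#' @param grid_shape Proton grid, voxels per axis (each >= 12). Default
#'   `c(64, 64, 24)`, a desk-scale stand-in for the acquisition's
#'   160 x 160 x 56 matrix (pass that for a full-size phantom).
#' @param fov_mm Field of view, mm (default 240 x 240 x 168); voxel size is
#'   `fov_mm / grid_shape`.
#' @param na_inplane_factor Sodium-to-proton in-plane voxel size ratio.
#' @param pv_smoothing_mm Gaussian smoothing (mm) applied to the tissue
#'   label maps to create partial-volume probability maps; 0 gives crisp
#'   0/1 probabilities.
#' @param head_center,head_semi Fractional center and semi-axes of the
#'   outer head ellipsoid.
#' @param r_wm,r_gm Fractional radii (of the head semi-axes) bounding the
#'   WM core and the GM shell; CSF fills the remainder of the head.
#' @param ventricle_semi,ventricle_offset Fractional semi-axes and x-offset
#'   of the two ventricles.
#' @param eye_center_y,eye_offset_x,eye_semi Fractional eye placement and
#'   semi-axes.
#' @return A `phantom_spec` list.
#' @export
phantom_spec <- function(grid_shape = c(64L, 64L, 24L),
                         fov_mm = c(240, 240, 168),
                         na_inplane_factor = 1.9,
                         pv_smoothing_mm = 2,
                         head_center = c(0.5, 0.58, 0.5),
                         head_semi = c(0.40, 0.34, 0.62),
                         r_wm = 0.60, r_gm = 0.86,
                         ventricle_semi = c(0.055, 0.11, 0.28),
                         ventricle_offset = 0.09,
                         eye_center_y = 0.115, eye_offset_x = 0.15,
                         eye_semi = c(0.09, 0.09, 0.18)) {
  grid_shape <- as.integer(grid_shape)
  stopifnot(length(grid_shape) == 3, all(grid_shape >= 12),
            length(fov_mm) == 3, all(fov_mm > 0),
            na_inplane_factor > 1, pv_smoothing_mm >= 0,
            r_wm > 0, r_gm > r_wm, r_gm < 1)
  structure(list(grid_shape = grid_shape, fov_mm = fov_mm,
                 voxel_size_mm = fov_mm / grid_shape,
                 na_inplane_factor = na_inplane_factor,
                 na_shape = c(pmax(1L, as.integer(round(grid_shape[1:2] / na_inplane_factor))),
                              grid_shape[3]),
                 pv_smoothing_mm = pv_smoothing_mm,
                 head_center = head_center, head_semi = head_semi,
                 r_wm = r_wm, r_gm = r_gm,
                 ventricle_semi = ventricle_semi,
                 ventricle_offset = ventricle_offset,
                 eye_center_y = eye_center_y, eye_offset_x = eye_offset_x,
                 eye_semi = eye_semi),
            class = "phantom_spec")
}

#' Multi-subject multi-scan study design
#'
#' @param n_subjects Number of subjects (>= 2); default 10.
#' @param n_scans Scans per subject (>= 2); default 3.
#' @param seed Master seed; per-subject and per-scan child seeds derive
#'   deterministically from it.
#' @return A `study_design` list.
#' @export
study_design <- function(n_subjects = 10L, n_scans = 3L, seed = 1L) {
  stopifnot(n_subjects >= 2, n_scans >= 2)
  structure(list(n_subjects = as.integer(n_subjects),
                 n_scans = as.integer(n_scans), seed = as.integer(seed)),
            class = "study_design")
}

child_seed <- function(master, subject, scan = 0L) {
  as.integer((as.numeric(master) * 20011 + subject * 1009 + scan) %% 2147483629)
}

#' Tissue parameter population distribution
#'
#' Per-tissue population means, inter-subject SDs and intra-scan
#' (scan-to-scan) relative SDs for T1, T2, proton density and sodium
#' signal. The defaults encode the study conditions this package models:
#' means from the published per-tissue averages (e.g. GM T1 1450 ms, WM
#' 940 ms, CSF 2570 ms), inter-subject SDs as the square roots of the
#' published inter-subject variances, and intra-scan relative SDs as the
#' square roots of the published intra-subject variances divided by the
#' means. Eye (vitreous humor) values are package conventions chosen so
#' the eye is the brightest sodium compartment, the premise of the sodium
#' normalization.
#'
#' @param params Optional replacement data.frame with columns `tissue`,
#'   `param`, `mean`, `inter_sd`, `intra_rel_sd` covering tissues
#'   gm/wm/csf/eye and params t1/t2/pd/na.
#' @param noise_rel Direct-mode additive image noise, relative to the mean
#'   in-head map value (default 0.02).
#' @param epg_noise_sd Complex Gaussian noise SD added per fingerprint
#'   sample in EPG mode, absolute units for unit-amplitude CSF (default
#'   0.002).
#' @param na_noise_rel Sodium image noise SD relative to the eye mean
#'   (default 0.02).
#' @return A `tissue_distribution` list.
#' @export
tissue_distribution <- function(params = NULL, noise_rel = 0.02,
                                epg_noise_sd = 0.002, na_noise_rel = 0.02) {
  if (is.null(params)) {
    params <- rbind(
      data.frame(tissue = "gm",  param = c("t1", "t2", "pd", "na"),
                 mean = c(1450, 40, 0.87, 0.35),
                 inter_sd = sqrt(c(1344, 2.80, 1.2e-3, 2.8e-4)),
                 intra_rel_sd = sqrt(c(79, 0.07, 7.6e-4, 6.0e-5)) / c(1450, 40, 0.87, 0.35)),
      data.frame(tissue = "wm",  param = c("t1", "t2", "pd", "na"),
                 mean = c(940, 32, 0.66, 0.31),
                 inter_sd = sqrt(c(505, 1.1, 6.6e-4, 2.9e-4)),
                 intra_rel_sd = sqrt(c(6, 0.1, 2.9e-4, 8.2e-5)) / c(940, 32, 0.66, 0.31)),
      data.frame(tissue = "csf", param = c("t1", "t2", "pd", "na"),
                 mean = c(2570, 102, 1.0, 0.50),
                 inter_sd = c(sqrt(c(23650, 366)), 0.03, sqrt(4.3e-4)),
                 intra_rel_sd = c(sqrt(c(6860, 13)) / c(2570, 102), 0.01,
                                  sqrt(4.3e-4) / 0.50)),
      data.frame(tissue = "eye", param = c("t1", "t2", "pd", "na"),
                 mean = c(3000, 250, 1.0, 1.0),
                 inter_sd = c(100, 12, 0.02, 0.02),
                 intra_rel_sd = c(0.01, 0.01, 0.01, 0.01)))
  }
  stopifnot(all(c("tissue", "param", "mean", "inter_sd", "intra_rel_sd") %in% names(params)),
            all(params$mean > 0), all(params$inter_sd >= 0),
            all(params$intra_rel_sd >= 0),
            noise_rel >= 0, epg_noise_sd >= 0, na_noise_rel >= 0)
  na_means <- params[params$param == "na", ]
  eye_na <- na_means$mean[na_means$tissue == "eye"]
  if (length(eye_na) != 1 || any(na_means$mean[na_means$tissue != "eye"] >= eye_na))
    stop("eye sodium mean must be strictly the greatest compartment (normalization premise)")
  structure(list(params = params, noise_rel = noise_rel,
                 epg_noise_sd = epg_noise_sd, na_noise_rel = na_noise_rel),
            class = "tissue_distribution")
}

dist_value <- function(tab, tissue, param) {
  v <- tab$value[tab$tissue == tissue & tab$param == param]
  if (length(v) != 1) stop(sprintf("missing value for %s/%s", tissue, param))
  v
}

# separable truncated-Gaussian smoothing with row-normalized kernels
# (preserves constants exactly, so label probabilities keep summing to 1)
gaussian_smooth3d <- function(arr, sigma_mm, voxel_size_mm) {
  if (sigma_mm <= 0) return(arr)
  dm <- dim(arr)
  for (ax in 1:3) {
    sig <- sigma_mm / voxel_size_mm[ax]
    r <- ceiling(3 * sig)
    if (r < 1) next
    n <- dm[ax]
    K <- matrix(0, n, n)
    for (i in seq_len(n)) {
      j <- max(1, i - r):min(n, i + r)
      w <- exp(-((j - i)^2) / (2 * sig^2))
      K[i, j] <- w / sum(w)
    }
    perm <- c(ax, setdiff(1:3, ax))
    a <- aperm(arr, perm)
    sh <- dim(a)
    a <- K %*% matrix(a, n)
    dim(a) <- sh
    arr <- aperm(a, order(perm))
  }
  arr
}

# nearest-neighbour index map from the coarse sodium grid into the fine grid
na_index_map <- function(fine_shape, na_shape) {
  idx <- function(nc, nf) pmin(nf, pmax(1L, as.integer(round((seq_len(nc) - 0.5) * nf / nc + 0.5))))
  list(ix = idx(na_shape[1], fine_shape[1]),
       iy = idx(na_shape[2], fine_shape[2]),
       iz = idx(na_shape[3], fine_shape[3]))
}

#' Construct the phantom geometry
#'
#' Builds crisp tissue labels (WM core, GM shell, CSF shell + ventricles,
#' eyes) from the spec's ellipsoids, then smooths the label indicator maps
#' into partial-volume probability maps. Geometry is deterministic: no
#' randomness enters here.
#'
#' @param spec A [phantom_spec()].
#' @return List with `prob` (list of `gm`/`wm`/`csf`/`eye` probability
#'   arrays on the proton grid), `labels` (integer array: 0 background,
#'   1 GM, 2 WM, 3 CSF, 4 eye), `eye_roi` (binary, proton grid),
#'   `eye_roi_na` (binary, sodium grid), `head_mask`, `na_map_index`,
#'   `spec`.
#' @export
make_geometry <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  dm <- spec$grid_shape
  fx <- (seq_len(dm[1]) - 0.5) / dm[1]
  fy <- (seq_len(dm[2]) - 0.5) / dm[2]
  fz <- (seq_len(dm[3]) - 0.5) / dm[3]
  X <- array(rep(fx, times = dm[2] * dm[3]), dm)
  Y <- array(rep(rep(fy, each = dm[1]), times = dm[3]), dm)
  Z <- array(rep(fz, each = dm[1] * dm[2]), dm)
  rho2 <- function(cx, cy, cz, ax, ay, az)
    ((X - cx) / ax)^2 + ((Y - cy) / ay)^2 + ((Z - cz) / az)^2
  hc <- spec$head_center; hs <- spec$head_semi
  head_r2 <- rho2(hc[1], hc[2], hc[3], hs[1], hs[2], hs[3])
  labels <- array(0L, dm)
  labels[head_r2 <= 1] <- 3L                       # CSF outer shell
  labels[head_r2 <= spec$r_gm^2] <- 1L             # GM shell
  labels[head_r2 <= spec$r_wm^2] <- 2L             # WM core
  vs <- spec$ventricle_semi
  for (sgn in c(-1, 1)) {
    v <- rho2(hc[1] + sgn * spec$ventricle_offset, hc[2] + 0.02, hc[3],
              vs[1], vs[2], vs[3])
    labels[v <= 1] <- 3L                           # ventricular CSF
  }
  es <- spec$eye_semi
  eye <- array(FALSE, dm)
  for (sgn in c(-1, 1)) {
    e <- rho2(0.5 + sgn * spec$eye_offset_x, spec$eye_center_y, 0.5,
              es[1], es[2], es[3])
    eye <- eye | (e <= 1)
  }
  if (any(eye & labels > 0L)) stop("eye compartment overlaps the head; adjust the spec")
  labels[eye] <- 4L
  counts <- tabulate(labels + 1L, nbins = 5L)
  if (any(counts[2:5] == 0))
    stop("degenerate geometry: a tissue compartment is empty at this grid size")
  prob <- lapply(c(gm = 1L, wm = 2L, csf = 3L, eye = 4L), function(l)
    gaussian_smooth3d(array(as.numeric(labels == l), dm),
                      spec$pv_smoothing_mm, spec$voxel_size_mm))
  nmap <- na_index_map(dm, spec$na_shape)
  eye_na <- array((labels == 4L)[nmap$ix, nmap$iy, nmap$iz], spec$na_shape)
  if (!any(eye_na)) stop("eye ROI empty on the sodium grid; enlarge the eyes or the grid")
  list(prob = prob, labels = labels, eye_roi = labels == 4L,
       eye_roi_na = eye_na, head_mask = labels %in% 1:3,
       na_map_index = nmap, spec = spec)
}

#' Draw one subject's true tissue parameters
#'
#' Each parameter is drawn from a normal distribution with the population
#' mean and inter-subject SD, redrawing any value below 10\% of its mean
#' (a truncation that keeps all parameters physically positive).
#' Deterministic given the seed.
#'
#' @param dist A [tissue_distribution()].
#' @param seed Integer seed.
#' @return Data.frame `tissue`, `param`, `value`.
#' @export
sample_subject <- function(dist, seed) {
  stopifnot(inherits(dist, "tissue_distribution"))
  set.seed(seed)
  p <- dist$params
  value <- numeric(nrow(p))
  for (i in seq_len(nrow(p))) {
    repeat {
      v <- rnorm(1, p$mean[i], p$inter_sd[i])
      if (v >= 0.1 * p$mean[i]) break
    }
    value[i] <- v
  }
  data.frame(tissue = p$tissue, param = p$param, value = value)
}

# smooth multiplicative transmit-field bowl over the head (low-order radial
# polynomial spanning b1_range), or a flat field
b1_field_map <- function(spec, type = c("bowl", "flat"), b1_range = c(0.7, 1.3),
                         b1_flat = 1) {
  type <- match.arg(type)
  dm <- spec$grid_shape
  if (type == "flat") return(array(b1_flat, dm))
  fx <- (seq_len(dm[1]) - 0.5) / dm[1] - 0.5
  fy <- (seq_len(dm[2]) - 0.5) / dm[2] - 0.5
  fz <- (seq_len(dm[3]) - 0.5) / dm[3] - 0.5
  X <- array(rep(fx, times = dm[2] * dm[3]), dm)
  Y <- array(rep(rep(fy, each = dm[1]), times = dm[3]), dm)
  Z <- array(rep(fz, each = dm[1] * dm[2]), dm)
  r2 <- (X^2 + Y^2 + Z^2) / 0.75
  r2[r2 > 1] <- 1
  b1_range[2] - (b1_range[2] - b1_range[1]) * r2
}

#' Simulate one scan of one subject
#'
#' Applies a scan-level multiplicative log-normal perturbation (the
#' intra-scan variation) to the subject's true tissue parameters, builds
#' voxelwise true maps as partial-volume mixtures of the tissue values,
#' and produces the measurement according to `mode`:
#' \describe{
#'   \item{direct}{noisy quantitative maps: true maps plus additive
#'     Gaussian noise (`noise_rel` of the mean in-head value).}
#'   \item{epg}{per-voxel EPG fingerprints (crisp tissue labels, smooth
#'     multiplicative B1+ field) with additive complex Gaussian noise,
#'     ready for dictionary matching.}
#' }
#' The sodium image is sampled on the coarse sodium grid by
#' nearest-neighbour lookup plus noise.
#'
#' @param subject Data.frame from [sample_subject()].
#' @param geom Geometry from [make_geometry()].
#' @param dist A [tissue_distribution()].
#' @param mode `"direct"` or `"epg"`.
#' @param seed Integer seed for this scan.
#' @param train Pulse train (EPG mode; default [make_pulse_train()]).
#' @param b1_type,b1_range,b1_flat Transmit-field model (EPG mode).
#' @param max_order EPG truncation order.
#' @return An `mrf_scan` list with `true` (maps + scan tissue values),
#'   `measured` (direct mode), `fingerprints`/`vox` (EPG mode),
#'   `na_image`, `b1_map`, `mode`, `seed`.
#' @export
simulate_scan <- function(subject, geom, dist, mode = c("direct", "epg"),
                          seed = 1L, train = NULL,
                          b1_type = c("bowl", "flat"), b1_range = c(0.7, 1.3),
                          b1_flat = 1, max_order = NULL) {
  mode <- match.arg(mode)
  b1_type <- match.arg(b1_type)
  stopifnot(inherits(dist, "tissue_distribution"))
  spec <- geom$spec
  set.seed(seed)
  p <- dist$params
  sdlog <- sqrt(log(1 + p$intra_rel_sd^2))
  fac <- exp(rnorm(nrow(p), -sdlog^2 / 2, sdlog))  # unit-mean multiplicative
  scan_tab <- data.frame(tissue = p$tissue, param = p$param,
                         value = subject$value * fac)
  dm <- spec$grid_shape
  mix <- function(param) {
    m <- array(0, dm)
    for (t in c("gm", "wm", "csf", "eye"))
      m <- m + geom$prob[[t]] * dist_value(scan_tab, t, param)
    m
  }
  true_maps <- list(pd = mix("pd"), t1 = mix("t1"), t2 = mix("t2"), na = mix("na"))
  b1_map <- b1_field_map(spec, b1_type, b1_range, b1_flat)
  region <- geom$head_mask | geom$eye_roi

  nmap <- geom$na_map_index
  na_img <- array(true_maps$na[nmap$ix, nmap$iy, nmap$iz], spec$na_shape)
  if (dist$na_noise_rel > 0) {
    eye_ref <- dist_value(scan_tab, "eye", "na")
    na_img <- na_img + array(rnorm(prod(spec$na_shape), 0,
                                   dist$na_noise_rel * eye_ref), spec$na_shape)
  }

  out <- list(mode = mode, seed = seed, true = true_maps,
              scan_values = scan_tab, b1_map = b1_map, na_image = na_img)
  if (mode == "direct") {
    measured <- lapply(true_maps[c("pd", "t1", "t2")], function(m) {
      if (dist$noise_rel > 0) {
        sd0 <- dist$noise_rel * mean(m[region])
        m[region] <- m[region] + rnorm(sum(region), 0, sd0)
      }
      m
    })
    measured$b1 <- b1_map
    out$measured <- measured
  } else {
    if (is.null(train)) train <- make_pulse_train()
    if (is.null(max_order)) max_order <- min(train$n_pulses, 100L)
    vox <- which(region)
    lab <- geom$labels[vox]
    tn <- c("gm", "wm", "csf", "eye")[lab]
    val <- function(param) vapply(tn, dist_value, numeric(1), tab = scan_tab,
                                  param = param)
    fp <- cpp_epg_fingerprints(val("t1"), val("t2"), b1_map[vox], val("pd"),
                               train$flip_deg, train$phase_deg,
                               train$pre_delay_ms, train$tr, train$te,
                               as.integer(max_order), FALSE, 0)
    if (dist$epg_noise_sd > 0)
      fp <- fp + matrix(complex(real = rnorm(length(fp), 0, dist$epg_noise_sd),
                                imaginary = rnorm(length(fp), 0, dist$epg_noise_sd)),
                        nrow(fp), ncol(fp))
    out$fingerprints <- fp
    out$vox <- vox
    out$train <- train
  }
  class(out) <- "mrf_scan"
  out
}

#' Generate a complete repeatability study
#'
#' `n_subjects` x `n_scans` simulated scans sharing one phantom geometry;
#' subject parameters and scan perturbations use child seeds derived
#' deterministically from the design's master seed, so regeneration with
#' the same design is bit-identical.
#'
#' @param design A [study_design()].
#' @param spec A [phantom_spec()].
#' @param dist A [tissue_distribution()].
#' @param mode `"direct"` or `"epg"`.
#' @param geometry Optional precomputed [make_geometry()] result (reused
#'   across replicate studies for speed).
#' @param ... Passed to [simulate_scan()].
#' @return An `mrf_study`: `design`, `spec`, `dist`, `geometry`,
#'   `subjects` (each with `params` and `scans`).
#' @export
generate_study <- function(design, spec = phantom_spec(),
                           dist = tissue_distribution(),
                           mode = c("direct", "epg"), geometry = NULL, ...) {
  mode <- match.arg(mode)
  stopifnot(inherits(design, "study_design"))
  if (is.null(geometry)) geometry <- make_geometry(spec)
  subjects <- vector("list", design$n_subjects)
  for (s in seq_len(design$n_subjects)) {
    params <- sample_subject(dist, child_seed(design$seed, s, 0L))
    scans <- lapply(seq_len(design$n_scans), function(k)
      simulate_scan(params, geometry, dist, mode,
                    seed = child_seed(design$seed, s, k), ...))
    subjects[[s]] <- list(id = s, params = params, scans = scans)
  }
  structure(list(design = design, spec = spec, dist = dist,
                 geometry = geometry, subjects = subjects, mode = mode),
            class = "mrf_study")
}

#' @export
print.mrf_study <- function(x, ...) {
  cat(sprintf("MRF repeatability study: %d subjects x %d scans (%s mode)\n",
              x$design$n_subjects, x$design$n_scans, x$mode))
  cat(sprintf("  proton grid %s | sodium grid %s | seed %d\n",
              paste(x$spec$grid_shape, collapse = "x"),
              paste(x$spec$na_shape, collapse = "x"), x$design$seed))
  invisible(x)
}
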