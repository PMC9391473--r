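#' Mean and SD of a map over a mask
#'
#' @param map Numeric array.
#' @param mask Logical array, same geometry, with at least 2 voxels (the
#'   sample SD is undefined for a single voxel).
#' @return Named vector `c(mean, sd)` (sample SD, n - 1 denominator).
#' @export
per_scan_summary <- function(map, mask) {
  stopifnot(all(dim(map) == dim(mask)))
  n <- sum(mask)
  if (n == 0) stop("empty mask")
  if (n == 1) stop("mask with a single voxel: SD undefined")
  v <- map[mask]
  c(mean = mean(v), sd = sd(v))
}

#' Pooled mean and SD over all subject-scan values
#'
#' @param values Numeric vector of one value per scan, pooled over
#'   subjects and scans (length >= 2).
#' @return Named vector `c(mean_all, sd_all)`.
#' @export
overall_summary <- function(values) {
  if (length(values) < 2) stop("need at least 2 values")
  c(mean_all = mean(values), sd_all = sd(values))
}

check_grouping <- function(values, subject) {
  stopifnot(length(values) == length(subject))
  split(values, subject)
}

#' Mean intra-subject (scan-to-scan) variance
#'
#' Mean over subjects of the within-subject sample variance of that
#' subject's scans.
#'
#' @param values Numeric vector, one value per scan.
#' @param subject Subject identifier aligned with `values`; every subject
#'   needs at least 2 scans.
#' @return Variance (squared units of the measurement).
#' @export
intra_var <- function(values, subject) {
  g <- check_grouping(values, subject)
  ns <- lengths(g)
  if (any(ns < 2)) stop("every subject needs at least 2 scans")
  mean(vapply(g, var, numeric(1)))
}

#' Inter-subject variance
#'
#' Sample variance of the per-subject mean values.
#'
#' @inheritParams intra_var
#' @return Variance (squared units of the measurement).
#' @export
inter_var <- function(values, subject) {
  g <- check_grouping(values, subject)
  if (length(g) < 2) stop("need at least 2 subjects")
  var(vapply(g, mean, numeric(1)))
}

#' Coefficient of variation (percent)
#'
#' 100 times the mean over subjects of each subject's scan SD divided by
#' that subject's scan mean. 0\% for perfectly repeatable measurements;
#' invariant under positive rescaling of the values but not under shifts.
#'
#' @inheritParams intra_var
#' @return CV in percent.
#' @export
cv_percent <- function(values, subject) {
  g <- check_grouping(values, subject)
  ns <- lengths(g)
  if (any(ns < 2)) stop("every subject needs at least 2 scans")
  m <- vapply(g, mean, numeric(1))
  if (any(m <= 0)) stop("CV undefined: a subject mean is non-positive")
  s <- vapply(g, sd, numeric(1))
  100 * mean(s / m)
}

#' Intraclass correlation from variance components
#'
#' `inter / (inter + intra)`, in \[0, 1\]: the fraction of total variance
#' attributable to true differences between subjects.
#'
#' @param inter Inter-subject variance (>= 0).
#' @param intra Intra-subject variance (>= 0).
#' @return ICC in \[0, 1\].
#' @export
icc <- function(inter, intra) {
  stopifnot(inter >= 0, intra >= 0)
  if (inter + intra == 0) stop("ICC undefined: both variance components are zero")
  inter / (inter + intra)
}

#' Qualitative band for a CV value
#'
#' Very good if CV <= 10\%, good if 10 < CV <= 20, moderate if
#' 20 < CV <= 30, poor above 30 (poor supersedes moderate).
#'
#' @param cv CV in percent (vectorized; `NA` passes through).
#' @return Character vector of bands.
#' @export
classify_cv <- function(cv) {
  if (any(cv < 0, na.rm = TRUE)) stop("negative CV")
  out <- rep(NA_character_, length(cv))
  ok <- !is.na(cv)
  out[ok] <- ifelse(cv[ok] <= 10, "very good",
             ifelse(cv[ok] <= 20, "good",
             ifelse(cv[ok] <= 30, "moderate", "poor")))
  out
}

#' Qualitative band for an ICC value
#'
#' Very good if ICC >= 0.8, good in \[0.6, 0.8), fair/moderate in
#' \[0.4, 0.6), poor below 0.4.
#'
#' @param x ICC in \[0, 1\] (vectorized; `NA` passes through).
#' @return Character vector of bands.
#' @export
classify_icc <- function(x) {
  if (any(x < 0 | x > 1, na.rm = TRUE)) stop("ICC must lie in [0, 1]")
  out <- rep(NA_character_, length(x))
  ok <- !is.na(x)
  out[ok] <- ifelse(x[ok] >= 0.8, "very good",
             ifelse(x[ok] >= 0.6, "good",
             ifelse(x[ok] >= 0.4, "fair/moderate", "poor")))
  out
}

#' Smallest detectable change (percent)
#'
#' Twice the CV: a conservative bound on the relative change in a mean
#' value that the method can distinguish from test-retest noise.
#'
#' @param cv CV in percent.
#' @return 2 x CV, percent.
#' @export
detectable_change <- function(cv) {
  stopifnot(all(cv >= 0, na.rm = TRUE))
  2 * cv
}

measurement_keys <- function() {
  expand.grid(statistic = c("mean", "sd"), tissue = c("GM", "WM", "CSF"),
              parameter = c("PD", "T1", "T2", "Na"),
              KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)[, 3:1]
}

#' Build the repeatability table
#'
#' One row per (parameter, tissue, statistic) key: pooled mean and SD,
#' inter- and intra-subject variance, CV, ICC, qualitative bands and the
#' detectable-change threshold (2 x CV). The (PD, CSF, mean) cell is the
#' normalization's defined constant 1 and carries not-applicable markers
#' instead of variability statistics, as does the ICC of any
#' zero-variance measurement.
#'
#' @param summaries Long-format data.frame with columns `subject`, `scan`,
#'   `parameter`, `tissue`, `statistic`, `value` (the schema of
#'   [summarize_study()] and of ingested per-scan CSV files).
#' @return A `repeatability_table` data.frame (24 rows for the standard
#'   four parameters and three tissues).
#' @export
build_table <- function(summaries) {
  need <- c("subject", "scan", "parameter", "tissue", "statistic", "value")
  stopifnot(all(need %in% names(summaries)))
  keys <- measurement_keys()
  missing_keys <- character(0)
  rows <- lapply(seq_len(nrow(keys)), function(i) {
    k <- keys[i, ]
    row <- data.frame(parameter = k$parameter, tissue = k$tissue,
                      statistic = k$statistic, mean_all = NA_real_,
                      sd_all = NA_real_, inter_var = NA_real_,
                      intra_var = NA_real_, cv_percent = NA_real_,
                      icc = NA_real_, cv_band = NA_character_,
                      icc_band = NA_character_,
                      detectable_change_percent = NA_real_)
    if (k$parameter == "PD" && k$tissue == "CSF" && k$statistic == "mean") {
      row$mean_all <- 1  # defined reference value of the CSF normalization
      return(row)
    }
    d <- summaries[summaries$parameter == k$parameter &
                   summaries$tissue == k$tissue &
                   summaries$statistic == k$statistic, ]
    if (nrow(d) == 0) {
      missing_keys <<- c(missing_keys,
                         paste(k$parameter, k$tissue, k$statistic, sep = "/"))
      return(row)
    }
    ov <- overall_summary(d$value)
    row$mean_all <- ov[["mean_all"]]; row$sd_all <- ov[["sd_all"]]
    row$inter_var <- inter_var(d$value, d$subject)
    row$intra_var <- intra_var(d$value, d$subject)
    row$cv_percent <- cv_percent(d$value, d$subject)
    row$icc <- if (row$inter_var + row$intra_var > 0)
      icc(row$inter_var, row$intra_var) else NA_real_
    row$cv_band <- classify_cv(row$cv_percent)
    row$icc_band <- classify_icc(row$icc)
    row$detectable_change_percent <- detectable_change(row$cv_percent)
    row
  })
  if (length(missing_keys) > 0)
    stop("missing measurement keys: ", paste(missing_keys, collapse = ", "))
  out <- do.call(rbind, rows)
  class(out) <- c("repeatability_table", "data.frame")
  out
}

#' @export
print.repeatability_table <- function(x, ...) {
  shown <- data.frame(parameter = x$parameter, tissue = x$tissue,
                      statistic = x$statistic,
                      mean_all = signif(x$mean_all, 3),
                      sd_all = signif(x$sd_all, 3),
                      inter_var = signif(x$inter_var, 3),
                      intra_var = signif(x$intra_var, 3),
                      cv_percent = round(x$cv_percent, 1),
                      icc = round(x$icc, 2),
                      icc_band = x$icc_band)
  print.data.frame(shown, row.names = FALSE)
  invisible(x)
}

#' Write / read a repeatability table (lossless CSV round-trip)
#'
#' Raw unrounded values are written with full precision; not-applicable
#' cells travel as empty fields.
#'
#' @param table A `repeatability_table`.
#' @param path CSV path.
#' @return `write_repeatability_table` returns `path` invisibly;
#'   `read_repeatability_table` the restored table.
#' @export
write_repeatability_table <- function(table, path) {
  tab <- as.data.frame(table)
  num <- vapply(tab, is.numeric, logical(1))
  for (j in which(num)) tab[[j]] <- sprintf("%.17g", tab[[j]])
  tab[tab == "NA"] <- ""
  write.csv(tab, path, row.names = FALSE, na = "")
  invisible(path)
}

#' @rdname write_repeatability_table
#' @export
read_repeatability_table <- function(path) {
  tab <- read.csv(path, stringsAsFactors = FALSE,
                  colClasses = c(parameter = "character", tissue = "character",
                                 statistic = "character"))
  for (j in c("mean_all", "sd_all", "inter_var", "intra_var", "cv_percent",
              "icc", "detectable_change_percent"))
    tab[[j]] <- as.numeric(tab[[j]])
  for (j in c("cv_band", "icc_band")) {
    tab[[j]] <- as.character(tab[[j]])
    tab[[j]][!is.na(tab[[j]]) & tab[[j]] == ""] <- NA_character_
  }
  class(tab) <- c("repeatability_table", "data.frame")
  tab
}

#' Attach matched parameter maps to an EPG-mode study
#'
#' Runs dictionary matching on every scan's fingerprint stack and stores
#' the resulting PD/T1/T2/B1 maps as that scan's measurement, after which
#' the study flows through [summarize_study()] exactly like a direct-mode
#' study.
#'
#' @param study An EPG-mode `mrf_study`.
#' @param dict An `mrf_dictionary` built with the study's pulse train.
#' @param chunk Voxels per matching block.
#' @return The study with `measured` maps filled in.
#' @export
match_study <- function(study, dict, chunk = 256L) {
  stopifnot(inherits(study, "mrf_study"))
  if (study$mode != "epg")
    stop("nothing to match: this is a direct-mode study (maps already exist)")
  dm <- study$spec$grid_shape
  for (s in seq_along(study$subjects)) {
    for (k in seq_along(study$subjects[[s]]$scans)) {
      scan <- study$subjects[[s]]$scans[[k]]
      res <- match_volume(scan$fingerprints, dict, chunk = chunk)
      blank <- array(NA_real_, dm)
      measured <- list()
      for (nm in c("pd", "t1", "t2")) {
        m <- blank; m[scan$vox] <- res[[nm]]; measured[[nm]] <- m
      }
      b1 <- blank; b1[scan$vox] <- res$b1_deg / dict$b1_ref_deg
      measured$b1 <- b1
      scan$measured <- measured
      study$subjects[[s]]$scans[[k]] <- scan
    }
  }
  study
}

#' Per-tissue per-scan summaries of one scan
#'
#' Binarizes the probability maps into non-overlapping masks, normalizes
#' PD by the CSF mean and sodium by the eye mean, and returns the mean and
#' SD of normalized PD, T1, T2 (proton grid) and normalized sodium
#' (sodium grid, masks resampled) in GM, WM and CSF.
#'
#' @param scan An `mrf_scan` carrying `measured` maps.
#' @param geom The study geometry.
#' @param threshold Mask binarization threshold (default 0.9).
#' @return Long-format data.frame `parameter`, `tissue`, `statistic`,
#'   `value`.
#' @export
summarize_scan <- function(scan, geom, threshold = 0.9) {
  if (is.null(scan$measured))
    stop("scan has no measured maps; run match_study() for EPG-mode studies")
  masks <- binarize_masks(geom$prob, threshold)
  if (!any(masks$csf)) stop("empty CSF mask at this threshold")
  pd_n <- normalize_pd(scan$measured$pd, masks$csf)
  na_n <- normalize_na(scan$na_image, geom$eye_roi_na)
  na_masks <- lapply(masks, resample_mask_to_na_grid, na_shape = dim(scan$na_image))
  rows <- list()
  tiss <- c(gm = "GM", wm = "WM", csf = "CSF")
  for (t in names(tiss)) {
    for (p in c("PD", "T1", "T2", "Na")) {
      if (p == "Na") {
        ms <- per_scan_summary(na_n, na_masks[[t]])
      } else {
        map <- switch(p, PD = pd_n, T1 = scan$measured$t1, T2 = scan$measured$t2)
        ms <- per_scan_summary(map, masks[[t]])
      }
      rows[[length(rows) + 1L]] <- data.frame(
        parameter = p, tissue = tiss[[t]], statistic = c("mean", "sd"),
        value = as.numeric(ms))
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Summarize every scan of a study
#'
#' @param study An `mrf_study` whose scans carry measured maps (direct
#'   mode, or EPG mode after [match_study()]).
#' @param threshold Mask binarization threshold.
#' @return Long-format data.frame `subject`, `scan`, `parameter`,
#'   `tissue`, `statistic`, `value` — the input schema of [build_table()].
#' @export
summarize_study <- function(study, threshold = 0.9) {
  stopifnot(inherits(study, "mrf_study"))
  rows <- list()
  for (s in seq_along(study$subjects)) {
    for (k in seq_along(study$subjects[[s]]$scans)) {
      sm <- summarize_scan(study$subjects[[s]]$scans[[k]], study$geometry, threshold)
      sm$subject <- s; sm$scan <- k
      rows[[length(rows) + 1L]] <- sm
    }
  }
  out <- do.call(rbind, rows)
  out[, c("subject", "scan", "parameter", "tissue", "statistic", "value")]
}
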