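#' Geometric parameter axis
#'
#' Values generated by repeated multiplication by `ratio` from `start`
#' while staying at or below `end` (a small relative tolerance absorbs
#' floating-point drift at the boundary).
#'
#' @param start First value (positive).
#' @param end Upper bound (inclusive).
#' @param ratio Multiplicative step (> 1), e.g. 1.05 for 5\% increments.
#' @return Numeric vector of grid values.
#' @export
geometric_grid <- function(start, end, ratio = 1.05) {
  stopifnot(start > 0, end >= start, ratio > 1)
  n <- floor(log(end / start) / log(ratio) + 1e-9) + 1L
  start * ratio^(seq_len(n) - 1L)
}

#' Dictionary grid over (T1, T2, B1+)
#'
#' The default grid is the acquisition's matching grid: T1 from 150 ms and
#' T2 from 15 ms, both in 5\% geometric steps up to 4347 ms and 435 ms
#' (70 values each), and a B1+ axis of achieved flip angles 10..130
#' degrees in 1 degree steps (121 values). B1+ is handled internally as a
#' multiplicative scale on the nominal train, `b1_deg / b1_ref_deg`.
#'
#' @param t1_min,t1_max T1 range, ms.
#' @param t2_min,t2_max T2 range, ms.
#' @param ratio Geometric step for the relaxation axes.
#' @param b1_deg Integer-degree B1+ axis.
#' @param b1_ref_deg Nominal reference angle mapping degrees to scale
#'   (scale = b1_deg / b1_ref_deg); default 70.
#' @param include_unphysical Keep grid entries with `t2 >= t1`? Default
#'   `FALSE`: no tissue has T2 exceeding T1, and dropping them shrinks the
#'   search space.
#' @return A `dictionary_grid` list with `t1_values`, `t2_values`,
#'   `b1_values` (degrees), `b1_ref_deg`, `include_unphysical`.
#' @export
dictionary_grid <- function(t1_min = 150, t1_max = 4347,
                            t2_min = 15, t2_max = 435, ratio = 1.05,
                            b1_deg = 10:130, b1_ref_deg = 70,
                            include_unphysical = FALSE) {
  stopifnot(all(b1_deg > 0), b1_ref_deg > 0)
  structure(list(t1_values = geometric_grid(t1_min, t1_max, ratio),
                 t2_values = geometric_grid(t2_min, t2_max, ratio),
                 b1_values = as.numeric(b1_deg),
                 b1_ref_deg = b1_ref_deg,
                 include_unphysical = isTRUE(include_unphysical)),
            class = "dictionary_grid")
}

#' Sliding-window average along the time dimension
#'
#' Groups consecutive samples into windows of `window_length` starting
#' every `window_stride` samples and averages each window; the same
#' operator is applied to measured fingerprints and to dictionary atoms so
#' that both live in the compressed time domain.
#'
#' @param signal Numeric or complex vector, or a matrix with time along
#'   rows (one fingerprint per column).
#' @param window_length Samples per window (>= 1, <= signal length).
#' @param window_stride Offset between window starts (>= 1).
#' @return Windowed vector (or matrix) of length
#'   `floor((n - window_length) / window_stride) + 1`.
#' @export
sliding_window <- function(signal, window_length = 8L, window_stride = 8L) {
  window_length <- as.integer(window_length); window_stride <- as.integer(window_stride)
  if (is.matrix(signal)) {
    n <- nrow(signal)
  } else n <- length(signal)
  if (window_length < 1 || window_stride < 1) stop("window length and stride must be >= 1")
  if (window_length > n) stop("window longer than the signal")
  starts <- seq(1L, n - window_length + 1L, by = window_stride)
  if (is.matrix(signal)) {
    out <- matrix(if (is.complex(signal)) 0i else 0, length(starts), ncol(signal))
    for (w in seq_along(starts)) {
      idx <- starts[w]:(starts[w] + window_length - 1L)
      out[w, ] <- colMeans(signal[idx, , drop = FALSE])
    }
    out
  } else {
    vapply(starts, function(s) mean(signal[s:(s + window_length - 1L)]),
           if (is.complex(signal)) complex(1) else numeric(1))
  }
}

#' Build an MRF dictionary
#'
#' Simulates one EPG fingerprint per retained (T1, T2, B1+) grid entry at
#' unit m0, applies the sliding-window average, and L2-normalizes each
#' atom, keeping the pre-normalization norms so matched amplitudes recover
#' proton density linearly. Entries with `t2 >= t1` are excluded unless
#' the grid allows them; the number excluded is reported as an attribute.
#'
#' @param grid A [dictionary_grid()].
#' @param train A [make_pulse_train()] object.
#' @param window_length,window_stride Sliding-window parameters (defaults
#'   8/8, a package convention; all results are window-agnostic).
#' @param max_order EPG truncation order (default `min(n_pulses, 100)`).
#' @param verbose Print progress.
#' @return An `mrf_dictionary`: `atoms` (complex matrix, windowed time x
#'   atoms, unit columns), `norms`, `params` (data.frame t1, t2, b1_deg,
#'   b1_scale, ordered ascending by (t1, t2, b1)), window and train
#'   metadata.
#' @export
build_dictionary <- function(grid, train, window_length = 8L,
                             window_stride = 8L, max_order = NULL,
                             verbose = FALSE) {
  stopifnot(inherits(grid, "dictionary_grid"), inherits(train, "pulse_train"))
  if (is.null(max_order)) max_order <- min(train$n_pulses, 100L)
  params <- expand.grid(b1_deg = grid$b1_values, t2 = grid$t2_values,
                        t1 = grid$t1_values, KEEP.OUT.ATTRS = FALSE)
  params <- params[, c("t1", "t2", "b1_deg")]
  n_total <- nrow(params)
  if (!grid$include_unphysical) params <- params[params$t2 < params$t1, , drop = FALSE]
  n_excluded <- n_total - nrow(params)
  if (nrow(params) == 0) stop("no physical grid entries remain")
  # lexicographic ascending order fixes the deterministic tie-break
  params <- params[order(params$t1, params$t2, params$b1_deg), , drop = FALSE]
  rownames(params) <- NULL
  params$b1_scale <- params$b1_deg / grid$b1_ref_deg
  if (verbose) message(sprintf("simulating %d fingerprints (%d unphysical entries excluded)",
                               nrow(params), n_excluded))
  raw <- cpp_epg_fingerprints(params$t1, params$t2, params$b1_scale,
                              rep(1, nrow(params)),
                              train$flip_deg, train$phase_deg,
                              train$pre_delay_ms, train$tr, train$te,
                              as.integer(max_order), FALSE, 0)
  atoms <- sliding_window(raw, window_length, window_stride)
  norms <- sqrt(colSums(Mod(atoms)^2))
  if (any(norms <= 0)) stop("zero-energy fingerprint encountered; check the train")
  atoms <- sweep(atoms, 2, norms, "/")
  structure(list(atoms = atoms, norms = norms, params = params,
                 window_length = as.integer(window_length),
                 window_stride = as.integer(window_stride),
                 max_order = as.integer(max_order),
                 n_excluded = n_excluded,
                 b1_ref_deg = grid$b1_ref_deg,
                 train = train),
            class = "mrf_dictionary")
}

#' @export
print.mrf_dictionary <- function(x, ...) {
  cat(sprintf("MRF dictionary: %d atoms x %d windowed samples\n",
              ncol(x$atoms), nrow(x$atoms)))
  cat(sprintf("  T1 %g..%g ms | T2 %g..%g ms | B1+ %g..%g deg (ref %g)\n",
              min(x$params$t1), max(x$params$t1),
              min(x$params$t2), max(x$params$t2),
              min(x$params$b1_deg), max(x$params$b1_deg), x$b1_ref_deg))
  cat(sprintf("  window %d / stride %d; %d unphysical entries excluded\n",
              x$window_length, x$window_stride, x$n_excluded))
  invisible(x)
}

window_signal_for <- function(dict, signal) {
  sliding_window(signal, dict$window_length, dict$window_stride)
}

#' Match one fingerprint against the dictionary
#'
#' Maximizes the normalized inner-product magnitude
#' `|<atom, s>| / ||s||` over atoms; ties resolve to the lowest
#' (t1, t2, b1) in lexicographic order (the atom ordering). The matched
#' amplitude `pd = |<atom, s>| / norm` is linear in m0 because atoms are
#' simulated at unit m0.
#'
#' @param signal Complex (or numeric) fingerprint already windowed
#'   identically to the dictionary (length `nrow(dict$atoms)`), or an
#'   unwindowed train-length signal which is windowed on the fly.
#' @param dict An `mrf_dictionary`.
#' @return List with `t1`, `t2`, `b1_deg`, `b1_scale`, `pd`, `score`.
#' @export
match_voxel <- function(signal, dict) {
  stopifnot(inherits(dict, "mrf_dictionary"))
  if (anyNA(signal)) stop("NaN/NA in signal")
  if (length(signal) != nrow(dict$atoms)) {
    signal <- window_signal_for(dict, signal)
    if (length(signal) != nrow(dict$atoms))
      stop("signal length matches neither the windowed nor the raw train length")
  }
  snorm <- sqrt(sum(Mod(signal)^2))
  if (snorm == 0) stop("all-zero signal: no match possible")
  ip <- Mod(crossprod(Conj(dict$atoms), as.complex(signal)))[, 1]
  best <- which.max(ip)
  list(t1 = dict$params$t1[best], t2 = dict$params$t2[best],
       b1_deg = dict$params$b1_deg[best], b1_scale = dict$params$b1_scale[best],
       pd = ip[best] / dict$norms[best], score = min(ip[best] / snorm, 1))
}

#' Match a fingerprint stack voxelwise
#'
#' @param signals Complex matrix, windowed (or raw) time along rows and
#'   one masked voxel per column, or a 4-D array (x, y, z, time).
#' @param dict An `mrf_dictionary`.
#' @param mask Logical 3-D array selecting voxels (required for array
#'   input; for matrix input the columns are taken as the masked voxels).
#' @param chunk Voxels per matching block (bounds memory).
#' @return For array input, a list of 3-D maps `t1`, `t2`, `b1_deg`, `pd`,
#'   `score` with `NA` outside the mask; for matrix input a data.frame
#'   with one row per column.
#' @export
match_volume <- function(signals, dict, mask = NULL, chunk = 256L) {
  stopifnot(inherits(dict, "mrf_dictionary"))
  as_array <- FALSE
  if (is.array(signals) && length(dim(signals)) == 4) {
    if (is.null(mask)) stop("mask required for 4-D input")
    dm <- dim(signals)
    if (!all(dim(mask) == dm[1:3])) stop("mask geometry does not match the stack")
    vox <- which(mask)
    sig <- matrix(0i, dm[4], length(vox))
    flat <- matrix(signals, prod(dm[1:3]), dm[4])
    sig[] <- t(flat[vox, , drop = FALSE])
    as_array <- TRUE
  } else {
    sig <- as.matrix(signals)
    vox <- seq_len(ncol(sig))
  }
  if (nrow(sig) != nrow(dict$atoms)) {
    sig <- window_signal_for(dict, sig)
    if (nrow(sig) != nrow(dict$atoms))
      stop("stack time dimension matches neither windowed nor raw train length")
  }
  nv <- ncol(sig)
  res <- data.frame(t1 = numeric(nv), t2 = numeric(nv), b1_deg = numeric(nv),
                    pd = numeric(nv), score = numeric(nv))
  if (anyNA(sig)) stop("NaN/NA in fingerprint stack")
  snorm <- sqrt(colSums(Mod(sig)^2))
  if (any(snorm == 0)) stop("all-zero fingerprint inside the mask")
  for (s in if (nv > 0) seq(1L, nv, by = chunk) else integer(0)) {
    j <- s:min(s + chunk - 1L, nv)
    ip <- Mod(crossprod(Conj(dict$atoms), sig[, j, drop = FALSE]))
    best <- apply(ip, 2, which.max)
    pick <- cbind(best, seq_along(j))
    res$t1[j] <- dict$params$t1[best]
    res$t2[j] <- dict$params$t2[best]
    res$b1_deg[j] <- dict$params$b1_deg[best]
    res$pd[j] <- ip[pick] / dict$norms[best]
    res$score[j] <- pmin(ip[pick] / snorm[j], 1)
  }
  if (!as_array) return(res)
  shape <- dim(mask)
  blank <- array(NA_real_, shape)
  out <- list()
  for (nm in names(res)) {
    m <- blank; m[vox] <- res[[nm]]; out[[nm]] <- m
  }
  out
}

#' Persist / load a dictionary
#'
#' The atom matrix is stored as an RDS binary container with a JSON
#' sidecar describing the grid ranges, window, exclusion policy and train.
#'
#' @param dict An `mrf_dictionary`.
#' @param path Base path; `.rds` and `.json` extensions are appended.
#' @return `write_dictionary` returns `path` invisibly; `read_dictionary`
#'   the restored `mrf_dictionary`.
#' @export
write_dictionary <- function(dict, path) {
  saveRDS(dict, paste0(path, ".rds"))
  meta <- list(n_atoms = ncol(dict$atoms), n_samples = nrow(dict$atoms),
               window_length = dict$window_length, window_stride = dict$window_stride,
               max_order = dict$max_order, n_excluded = dict$n_excluded,
               b1_ref_deg = dict$b1_ref_deg,
               t1_range = range(dict$params$t1), t2_range = range(dict$params$t2),
               b1_range = range(dict$params$b1_deg),
               train = list(n_pulses = dict$train$n_pulses, tr = dict$train$tr,
                            te = dict$train$te,
                            flip_checksum = round(sum(dict$train$flip_deg), 6)))
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_dictionary
#' @export
read_dictionary <- function(path) {
  d <- readRDS(paste0(path, ".rds"))
  stopifnot(inherits(d, "mrf_dictionary"))
  d
}
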