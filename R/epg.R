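#' Tissue parameter set for fingerprint simulation
#'
#' Bundles the relaxation and amplitude parameters of a single tissue
#' (or voxel) as consumed by [simulate_fingerprint()].
#'
#' @param t1 Longitudinal relaxation time, ms. Must be positive.
#' @param t2 Transverse relaxation time, ms. Must be positive.
#' @param m0 Equilibrium magnetization amplitude, arbitrary units
#'   (proton density up to a receive-chain scale). Must be non-negative.
#' @param b1 Transmit-field scale: dimensionless multiplier applied to all
#'   nominal flip angles of the pulse train. Must be positive.
#' @param allow_unphysical If `FALSE` (default) reject `t2 > t1`, which no
#'   real tissue exhibits. Dictionary construction may permit such entries
#'   explicitly.
#' @return An object of class `tissue_params`.
#' @export
tissue_params <- function(t1, t2, m0 = 1, b1 = 1, allow_unphysical = FALSE) {
  stopifnot(is.numeric(t1), is.numeric(t2), is.numeric(m0), is.numeric(b1),
            length(t1) == 1, length(t2) == 1, length(m0) == 1, length(b1) == 1)
  if (!is.finite(t1) || t1 <= 0) stop("t1 must be a positive finite number (ms)")
  if (!is.finite(t2) || t2 <= 0) stop("t2 must be a positive finite number (ms)")
  if (!is.finite(m0) || m0 < 0) stop("m0 must be non-negative")
  if (!is.finite(b1) || b1 <= 0) stop("b1 must be positive")
  if (!allow_unphysical && t2 > t1)
    stop("t2 > t1 is non-physical; pass allow_unphysical = TRUE to permit it")
  structure(list(t1 = t1, t2 = t2, m0 = m0, b1 = b1), class = "tissue_params")
}

#' Variable flip-angle MRF pulse train
#'
#' Generates the gradient-spoiled (FISP-type) fingerprinting train used by
#' the simulator: segments of sinusoidal flip-angle ramps between a floor
#' and per-segment ceiling, constant RF phase (no RF spoiling), fixed TR/TE.
#' The actual train of the acquisition this package models is vendor
#' configuration, so the generator here is a documented package convention;
#' every downstream computation is train-agnostic and accepts any train.
#'
#' @param n_pulses Number of RF pulses (default 420).
#' @param n_segments Number of shots/segments the train is divided into
#'   (default 6); `n_pulses` must be divisible by `n_segments`.
#' @param flip_floor Minimum nominal flip angle, degrees.
#' @param flip_ceilings Per-segment peak nominal flip angles, degrees;
#'   recycled to `n_segments`.
#' @param phase_deg Constant RF phase, degrees (FISP convention).
#' @param tr Repetition time, ms.
#' @param te Echo time, ms.
#' @param segment_gap_ms Delay inserted before each segment after the first
#'   (relaxation only), ms.
#' @return An object of class `pulse_train` with fields `flip_deg`,
#'   `phase_deg`, `pre_delay_ms` (per-pulse delay applied before the pulse),
#'   `tr`, `te`, `n_pulses`, `segment_starts`.
#' @export
make_pulse_train <- function(n_pulses = 420L, n_segments = 6L,
                             flip_floor = 10,
                             flip_ceilings = c(60, 45, 70, 50, 65, 40),
                             phase_deg = 0, tr = 7.5, te = 2,
                             segment_gap_ms = 0) {
  n_pulses <- as.integer(n_pulses); n_segments <- as.integer(n_segments)
  stopifnot(n_pulses >= 1, n_segments >= 1, n_pulses %% n_segments == 0,
            tr > te, te > 0, segment_gap_ms >= 0, flip_floor >= 0)
  seg_len <- n_pulses %/% n_segments
  ceilings <- rep_len(flip_ceilings, n_segments)
  flips <- unlist(lapply(seq_len(n_segments), function(s) {
    flip_floor + (ceilings[s] - flip_floor) * sin(pi * seq_len(seg_len) / (seg_len + 1))
  }))
  starts <- seq(1L, n_pulses, by = seg_len)
  pre <- numeric(n_pulses)
  if (segment_gap_ms > 0 && n_segments > 1) pre[starts[-1]] <- segment_gap_ms
  pulse_train(flips, rep(phase_deg, n_pulses), tr, te, pre, starts)
}

#' Construct a pulse train from explicit per-pulse values
#'
#' Lower-level companion of [make_pulse_train()] for arbitrary flip/phase
#' patterns (e.g. trains read from CSV or constant-flip validation trains).
#'
#' @param flip_deg,phase_deg Per-pulse nominal flip and RF phase, degrees.
#' @param tr,te Repetition and echo time, ms (`tr > te > 0`).
#' @param pre_delay_ms Per-pulse delay applied before the pulse, ms.
#' @param segment_starts Indices where shots/segments begin.
#' @return A `pulse_train`.
#' @export
pulse_train <- function(flip_deg, phase_deg, tr, te,
                        pre_delay_ms = numeric(length(flip_deg)),
                        segment_starts = 1L) {
  n <- length(flip_deg)
  stopifnot(length(phase_deg) == n, length(pre_delay_ms) == n,
            tr > te, te > 0, all(pre_delay_ms >= 0),
            all(is.finite(flip_deg)), all(is.finite(phase_deg)))
  structure(list(flip_deg = as.numeric(flip_deg),
                 phase_deg = as.numeric(phase_deg),
                 pre_delay_ms = as.numeric(pre_delay_ms),
                 tr = tr, te = te, n_pulses = n,
                 segment_starts = as.integer(segment_starts)),
            class = "pulse_train")
}

#' Read / write a pulse train as CSV
#'
#' Columns: `index`, `flip_deg`, `phase_deg` (and optionally `pre_delay_ms`).
#' TR and TE travel as commented header lines (`# tr_ms=`, `# te_ms=`).
#'
#' @param path File path.
#' @param train A `pulse_train`.
#' @return `read_pulse_train` returns a `pulse_train`;
#'   `write_pulse_train` returns `path` invisibly.
#' @export
read_pulse_train <- function(path) {
  hdr <- readLines(path, n = 10L)
  hdr <- hdr[startsWith(hdr, "#")]
  getv <- function(key, default) {
    m <- grep(paste0("^#\\s*", key, "="), hdr, value = TRUE)
    if (length(m) == 0) default else as.numeric(sub(paste0("^#\\s*", key, "="), "", m[1]))
  }
  tr <- getv("tr_ms", 7.5); te <- getv("te_ms", 2)
  df <- read.csv(path, comment.char = "#")
  pre <- if ("pre_delay_ms" %in% names(df)) df$pre_delay_ms else numeric(nrow(df))
  pulse_train(df$flip_deg, df$phase_deg, tr, te, pre)
}

#' @rdname read_pulse_train
#' @export
write_pulse_train <- function(train, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(sprintf("# tr_ms=%g", train$tr), sprintf("# te_ms=%g", train$te)), con)
  df <- data.frame(index = seq_len(train$n_pulses),
                   flip_deg = train$flip_deg, phase_deg = train$phase_deg,
                   pre_delay_ms = train$pre_delay_ms)
  write.csv(df, con, row.names = FALSE)
  invisible(path)
}

#' Extended phase graph state set
#'
#' Creates the equilibrium EPG configuration-state set: `Fp[k]`, `Fm[k]`
#' (complex transverse configuration amplitudes of dephasing order k = 0..K)
#' and `Z[k]` (longitudinal), with `Z[0] = m0` and all other states zero.
#'
#' @param max_order Highest retained dephasing order K.
#' @param m0 Equilibrium magnetization.
#' @return An `epg_state` list with complex vectors `Fp`, `Fm`, `Z` of
#'   length `max_order + 1`.
#' @export
epg_init <- function(max_order, m0 = 1) {
  stopifnot(max_order >= 1, m0 >= 0)
  n <- max_order + 1L
  z <- complex(n); z[1] <- m0 + 0i
  structure(list(Fp = complex(n), Fm = complex(n), Z = z,
                 max_order = as.integer(max_order)),
            class = "epg_state")
}

#' EPG RF pulse operator
#'
#' Applies the standard EPG rotation for an RF pulse of flip `alpha_deg`
#' and phase `phi_deg` to every configuration order. The operator mixes
#' (F+_k, F-_k, Z_k) with the usual 3x3 rotation matrix and conserves
#' sum(|F+|^2 + |F-|^2 + 2|Z|^2) per order (see [epg_energy()]).
#'
#' @param state An `epg_state`.
#' @param alpha_deg Flip angle, degrees.
#' @param phi_deg RF phase, degrees.
#' @return The transformed `epg_state`.
#' @export
epg_rf <- function(state, alpha_deg, phi_deg = 0) {
  a <- alpha_deg * pi / 180
  p <- phi_deg * pi / 180
  ca2 <- cos(a / 2)^2; sa2 <- sin(a / 2)^2; sa <- sin(a); caa <- cos(a)
  eip <- exp(1i * p); ei2p <- exp(2i * p)
  Fp <- state$Fp; Fm <- state$Fm; Z <- state$Z
  Fp2 <- ca2 * Fp + ei2p * sa2 * Fm - 1i * eip * sa * Z
  Fm2 <- Conj(ei2p) * sa2 * Fp + ca2 * Fm + 1i * Conj(eip) * sa * Z
  Z2 <- -0.5i * Conj(eip) * sa * Fp + 0.5i * eip * sa * Fm + caa * Z
  state$Fp <- Fp2; state$Fm <- Fm2; state$Z <- Z2
  state
}

#' EPG relaxation / regrowth operator
#'
#' Free evolution over `dt` ms: transverse states decay with T2,
#' longitudinal states with T1, and `Z[0]` regrows toward `m0`.
#'
#' @param state An `epg_state`.
#' @param dt Duration, ms (non-negative).
#' @param t1,t2 Relaxation times, ms.
#' @param m0 Equilibrium magnetization toward which `Z[0]` recovers.
#' @return The relaxed `epg_state`.
#' @export
epg_relax <- function(state, dt, t1, t2, m0 = 1) {
  stopifnot(dt >= 0, t1 > 0, t2 > 0)
  if (dt == 0) return(state)
  e1 <- exp(-dt / t1); e2 <- exp(-dt / t2)
  state$Fp <- state$Fp * e2
  state$Fm <- state$Fm * e2
  state$Z <- state$Z * e1
  state$Z[1] <- state$Z[1] + m0 * (1 - e1)
  state
}

#' EPG gradient shift operator
#'
#' Applies one unit of gradient dephasing (the unbalanced spoiler of a
#' FISP-type TR): F+ orders move up by one, F- orders move down, with the
#' order passing through zero transferred conjugately (F+_0 = conj(F-_0)
#' after the shift). Longitudinal states are unaffected; amplitudes pushed
#' beyond `max_order` are dropped (truncation).
#'
#' @param state An `epg_state`.
#' @return The shifted `epg_state`.
#' @export
epg_shift <- function(state) {
  n <- state$max_order + 1L
  Fp <- state$Fp; Fm <- state$Fm
  state$Fp <- c(0i, Fp[-n])
  state$Fm <- c(Fm[-1], 0i)
  state$Fp[1] <- Conj(state$Fm[1])
  state
}

#' Conserved quadratic form of the EPG RF rotation
#'
#' Returns sum over orders of |F+|^2 + |F-|^2 + 2 |Z|^2, the quantity the
#' RF operator leaves invariant (the transverse configuration pair F+/F-
#' double-counts magnetization relative to Z, hence the factor 2).
#'
#' @param state An `epg_state`.
#' @return A non-negative scalar.
#' @export
epg_energy <- function(state) {
  sum(Mod(state$Fp)^2 + Mod(state$Fm)^2 + 2 * Mod(state$Z)^2)
}

#' Simulate an MRF fingerprint with the EPG formalism
#'
#' Evolves the magnetization of one tissue through the gradient-spoiled
#' variable flip-angle train: per pulse, any inter-segment delay is relaxed
#' through, the RF rotation is applied at the effective flip `b1 *
#' flip_deg`, the state relaxes over TE where the complex signal F+_0 is
#' sampled, relaxes over TR - TE, and is dephased by the spoiler shift.
#'
#' @param tissue A [tissue_params()] object.
#' @param train A [make_pulse_train()] object.
#' @param max_order Highest retained dephasing order; default
#'   `min(n_pulses, 100)`.
#' @param inversion_prep If `TRUE`, prepend an adiabatic-style 180 degree
#'   inversion followed by `inversion_delay_ms` of relaxation (off by
#'   default; the modeled acquisition does not use one).
#' @param inversion_delay_ms Delay after the inversion pulse, ms.
#' @param engine `"compiled"` (Rcpp batch kernel, default) or
#'   `"reference"` (pure-R operator composition); both paths are tested to
#'   agree to near machine precision.
#' @return Complex vector of length `n_pulses` (the fingerprint); take
#'   `Mod()` for the magnitude signal.
#' @export
simulate_fingerprint <- function(tissue, train, max_order = NULL,
                                 inversion_prep = FALSE,
                                 inversion_delay_ms = 20,
                                 engine = c("compiled", "reference")) {
  engine <- match.arg(engine)
  stopifnot(inherits(tissue, "tissue_params"), inherits(train, "pulse_train"))
  if (is.null(max_order)) max_order <- min(train$n_pulses, 100L)
  max_order <- as.integer(max_order)
  stopifnot(max_order >= 1)
  if (engine == "compiled") {
    m <- cpp_epg_fingerprints(tissue$t1, tissue$t2, tissue$b1, tissue$m0,
                              train$flip_deg, train$phase_deg,
                              train$pre_delay_ms, train$tr, train$te,
                              max_order, inversion_prep, inversion_delay_ms)
    return(drop(m))
  }
  st <- epg_init(max_order, tissue$m0)
  if (inversion_prep) {
    st <- epg_rf(st, 180, 0)
    st <- epg_relax(st, inversion_delay_ms, tissue$t1, tissue$t2, tissue$m0)
  }
  sig <- complex(train$n_pulses)
  for (j in seq_len(train$n_pulses)) {
    if (train$pre_delay_ms[j] > 0)
      st <- epg_relax(st, train$pre_delay_ms[j], tissue$t1, tissue$t2, tissue$m0)
    st <- epg_rf(st, tissue$b1 * train$flip_deg[j], train$phase_deg[j])
    st <- epg_relax(st, train$te, tissue$t1, tissue$t2, tissue$m0)
    sig[j] <- st$Fp[1]
    st <- epg_relax(st, train$tr - train$te, tissue$t1, tissue$t2, tissue$m0)
    st <- epg_shift(st)
  }
  sig
}

#' Spoiled gradient-echo (Ernst / FLASH) steady-state signal
#'
#' Closed-form steady-state magnitude at TE for an ideally spoiled
#' constant-flip gradient echo:
#' `m0 * sin(a) * (1 - E1) / (1 - E1 cos(a)) * exp(-te/t2)` with
#' `E1 = exp(-tr/t1)`. Used as the analytic limit the EPG simulator must
#' reproduce for a constant train when T2 << TR (complete spoiling).
#'
#' @param alpha_deg Flip angle, degrees.
#' @param t1,t2 Relaxation times, ms.
#' @param tr,te Repetition and echo times, ms.
#' @param m0 Equilibrium magnetization.
#' @return Steady-state signal magnitude.
#' @export
ernst_signal <- function(alpha_deg, t1, t2, tr, te, m0 = 1) {
  a <- alpha_deg * pi / 180
  e1 <- exp(-tr / t1)
  m0 * sin(a) * (1 - e1) / (1 - e1 * cos(a)) * exp(-te / t2)
}
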