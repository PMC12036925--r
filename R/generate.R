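#' Default six-direction diffusion gradient scheme
#'
#' The classic dual-gradient six-direction set (normalized), non-coplanar and
#' well conditioned for a single-shell tensor fit.
#'
#' @return A 6 x 3 matrix of unit gradient directions.
#' @export
dti_directions <- function() {
  g <- rbind(c(1, 1, 0), c(1, -1, 0), c(0, 1, 1),
             c(0, -1, 1), c(1, 0, 1), c(-1, 0, 1))
  g / sqrt(rowSums(g^2))
}

#' Inversion-prepared variable-flip-angle fingerprint schedule
#'
#' A spoiled-gradient-echo fingerprint train: adiabatic inversion, a short
#' inversion delay, then `n_pulses` excitations. The default train interleaves
#' segments at very different flip levels (alternating 10-80 degrees every 25
#' pulses) with a sawtooth TR sweep from 12 to 900 ms. The flip-level
#' contrast separates the transmit-field (B1+) axis from T1, and the TR sweep
#' provides saturation-recovery T1 encoding with large signal excursions; a
#' constant-TR constant-ramp train leaves T1, B1 and fat fraction nearly
#' collinear under dictionary matching. The echo time enters through the fat
#' chemical-shift phase (see [generate_fingerprint_series()]); the default
#' 1.75 ms puts the fat resonance near quadrature with water at 3 T, which is
#' what makes the fat-fraction axis identifiable. The same schedule drives
#' both the phantom generator and the matching dictionary.
#'
#' @param n_pulses Number of excitations.
#' @param tr_ms Repetition times (ms); scalar or per-pulse vector. `NULL`
#'   gives the default sawtooth sweep.
#' @param ti_ms Delay between inversion and the first pulse (ms).
#' @param te_ms Echo time (ms), setting the fat-water phase.
#' @param flip_deg Per-pulse flip angles (degrees); `NULL` gives the default
#'   segmented pattern.
#' @return A list with elements `flip_deg`, `tr_ms`, `ti_ms`, `te_ms`.
#' @export
fingerprint_schedule <- function(n_pulses = 400, tr_ms = NULL, ti_ms = 20,
                                 te_ms = 1.75, flip_deg = NULL) {
  if (is.null(flip_deg)) {
    levels <- c(10, 70, 25, 55, 15, 80, 35, 45)
    flip_deg <- rep(rep(levels, each = 25), length.out = n_pulses)
  }
  n_pulses <- length(flip_deg)
  if (n_pulses < 1) stop("empty fingerprint schedule", call. = FALSE)
  if (is.null(tr_ms))
    tr_ms <- 12 + 888 * (seq_len(n_pulses) %% 89) / 89
  tr_ms <- rep_len(tr_ms, n_pulses)
  list(flip_deg = flip_deg, tr_ms = tr_ms, ti_ms = ti_ms, te_ms = te_ms)
}

#' Single-compartment fingerprint signal
#'
#' Longitudinal-magnetization recursion of an inversion-prepared spoiled
#' gradient echo: after inversion and a `ti_ms` recovery, each pulse n reads
#' out `Mz * sin(B1 * alpha_n)` and leaves `Mz * cos(B1 * alpha_n)` to relax
#' towards equilibrium over the following TR. Perfect spoiling of transverse
#' magnetization is assumed.
#'
#' @param t1_ms T1 values (ms), vectorized.
#' @param b1 Transmit-field scale (fraction of nominal), recycled to
#'   `length(t1_ms)`.
#' @param schedule A [fingerprint_schedule()].
#' @return Matrix `[length(t1_ms), n_pulses]` of signed signal time-courses.
#' @export
mrf_signal <- function(t1_ms, b1 = 1, schedule = fingerprint_schedule()) {
  b1 <- rep_len(b1, length(t1_ms))
  n <- length(schedule$flip_deg)
  out <- matrix(0, length(t1_ms), n)
  mz <- 1 - 2 * exp(-schedule$ti_ms / t1_ms)
  for (k in seq_len(n)) {
    th <- b1 * schedule$flip_deg[k] * pi / 180
    out[, k] <- mz * sin(th)
    mz <- 1 + (mz * cos(th) - 1) * exp(-schedule$tr_ms[k] / t1_ms)
  }
  out
}

# Per-voxel water/fat signal fractions; background voxels carry zero signal.
phantom_fractions <- function(truth) {
  idx <- which(truth$labels > 0)
  list(idx = idx, ffrac = truth$ff[idx] / 100)
}

#' Generate the three-echo Dixon gradient-echo series
#'
#' Complex forward model per voxel:
#' `S(TE) = (W + F exp(i 2 pi f_fat TE)) exp(i 2 pi psi TE) exp(-TE / T2*)`
#' with `W`, `F` set from the true fat fraction, the smooth off-resonance
#' field `psi`, a single-peak fat spectrum at `f_fat`, and a single common
#' T2* decay. Complex Gaussian noise of standard deviation `config$sigma` is
#' added to both channels.
#'
#' @param config A [phantom_config()].
#' @param truth Optional precomputed [phantom_ground_truth()].
#' @return An [acquisition_series()] with complex data and per-volume `te_ms`.
#' @export
generate_dixon_series <- function(config, truth = phantom_ground_truth(config)) {
  te <- config$dixon_te_ms
  if (any(diff(te) <= 0))
    stop("Dixon echo times must be strictly increasing", call. = FALSE)
  fr <- phantom_fractions(truth)
  fat_hz <- ppm_to_hz(config$constants$fat_ppm, config$constants$f0_mhz)
  d <- c(config$nx, config$ny, config$nz, length(te))
  dat <- array(complex(real = 0), d)
  psi <- truth$psi[fr$idx]
  t2s <- truth$t2star[fr$idx]
  w <- 1 - fr$ffrac; f <- fr$ffrac
  nvox <- prod(d[1:3])
  for (k in seq_along(te)) {
    tk <- te[k] / 1000  # s
    vol <- complex(real = rep(0, nvox))
    vol[fr$idx] <- (w + f * exp(2i * pi * fat_hz * tk)) *
      exp(2i * pi * psi * tk) * exp(-te[k] / t2s)
    if (config$sigma > 0)
      vol <- vol + with_seed(config$seed + 101 + k,
                             complex_noise(nvox, config$sigma))
    dat[, , , k] <- vol
  }
  acquisition_series(dat, tibble::tibble(volume = seq_along(te), te_ms = te),
                     "dixon", config$spacing,
                     extra = list(fat_hz = fat_hz))
}

#' Generate the 17-echo multi-echo spin-echo series
#'
#' Magnitude decay per voxel:
#' `S(TE) = A_w exp(-TE/T2w) + A_f (p1 exp(-TE/T2f1) + p2 exp(-TE/T2f2))`
#' with `A_f / (A_w + A_f)` equal to the true fat fraction, the two fat
#' components fixed at the shared constants, and the whole decay scaled by the
#' local B1+ weighting. Rician noise is realized by adding i.i.d. complex
#' Gaussian noise before taking magnitudes.
#'
#' @inheritParams generate_dixon_series
#' @return An [acquisition_series()] with real (magnitude) data and `te_ms`.
#' @export
generate_mse_series <- function(config, truth = phantom_ground_truth(config)) {
  te <- config$mse_te_ms
  fr <- phantom_fractions(truth)
  cs <- config$constants
  d <- c(config$nx, config$ny, config$nz, length(te))
  dat <- array(0, d)
  amp <- truth$b1[fr$idx]
  aw <- amp * (1 - fr$ffrac); af <- amp * fr$ffrac
  t2w <- truth$t2w[fr$idx]
  nvox <- prod(d[1:3])
  for (k in seq_along(te)) {
    vol <- rep(0, nvox)
    fatdecay <- sum(cs$fat_weights * exp(-te[k] / cs$fat_t2_ms))
    vol[fr$idx] <- aw * exp(-te[k] / t2w) + af * fatdecay
    if (config$sigma > 0) {
      vol <- Mod(vol + with_seed(config$seed + 202 + k,
                                 complex_noise(nvox, config$sigma)))
    }
    dat[, , , k] <- vol
  }
  acquisition_series(dat, tibble::tibble(volume = seq_along(te), te_ms = te),
                     "mse", config$spacing)
}

#' Generate a DOFS diffusion-weighted series at one mixing time
#'
#' For every gradient (one b = 0 plus `directions`) and every readout shift
#' `t_s` the complex signal is
#' `S = (W exp(-b g' D g) + F exp(i 2 pi f_olef t_s) exp(-b d_f))
#'      exp(i 2 pi psi t_s)`
#' where `D` is the voxel's true diffusion tensor, `F` the residual olefinic
#' fat left by SPAIR (offset `f_olef` from water) and `d_f` its apparent
#' diffusivity. The olefinic fat fraction is `olefinic_scale` times the muscle
#' fat fraction.
#'
#' @inheritParams generate_dixon_series
#' @param mixing_time_ms Stimulated-echo mixing time (ms); one of the study's
#'   100/200/300/400 by default, any non-negative value accepted.
#' @param directions Matrix of unit gradient directions (>= 6 rows).
#' @return An [acquisition_series()] with complex data and per-volume `bval`,
#'   `gx`, `gy`, `gz`, `shift_ms`, `tm_ms`, `diffusion_time_ms`.
#' @export
generate_dti_series <- function(config, mixing_time_ms = 100,
                                truth = phantom_ground_truth(config),
                                directions = dti_directions()) {
  if (nrow(directions) < 6)
    stop("at least 6 diffusion directions are required", call. = FALSE)
  shifts <- config$dti_shifts_ms
  cs <- config$constants
  olef_hz <- ppm_to_hz(cs$olefinic_ppm, cs$f0_mhz)
  fr <- phantom_fractions(truth)
  o <- pmin(config$olefinic_scale * fr$ffrac * 100, 60) / 100
  w <- 1 - o
  tens <- matrix(truth$tensor, ncol = 6)[fr$idx, , drop = FALSE]
  psi <- truth$psi[fr$idx]
  grads <- rbind(c(0, 0, 0), directions)
  bvals <- c(0, rep(config$dti_bval, nrow(directions)))
  nvol <- nrow(grads) * length(shifts)
  d <- c(config$nx, config$ny, config$nz, nvol)
  dat <- array(complex(real = 0), d)
  meta <- vector("list", nvol)
  nvox <- prod(d[1:3])
  vol_i <- 0L
  for (gi in seq_len(nrow(grads))) {
    g <- grads[gi, ]
    gDg <- tens[, 1] * g[1]^2 + tens[, 2] * g[2]^2 + tens[, 3] * g[3]^2 +
      2 * (tens[, 4] * g[1] * g[2] + tens[, 5] * g[1] * g[3] +
             tens[, 6] * g[2] * g[3])
    att_w <- exp(-bvals[gi] * gDg * 1e-3)     # D in um^2/ms = 1e-3 mm^2/s
    att_f <- exp(-bvals[gi] * cs$olefinic_adc * 1e-3)
    for (si in seq_along(shifts)) {
      vol_i <- vol_i + 1L
      ts <- shifts[si] / 1000
      vol <- complex(real = rep(0, nvox))
      vol[fr$idx] <- (w * att_w + o * exp(2i * pi * olef_hz * ts) * att_f) *
        exp(2i * pi * psi * ts)
      if (config$sigma > 0)
        vol <- vol + with_seed(config$seed + 303 + round(mixing_time_ms) +
                                 vol_i, complex_noise(nvox, config$sigma))
      dat[, , , vol_i] <- vol
      meta[[vol_i]] <- tibble::tibble(
        volume = vol_i, bval = bvals[gi],
        gx = g[1], gy = g[2], gz = g[3], shift_ms = shifts[si],
        tm_ms = mixing_time_ms,
        diffusion_time_ms = compute_diffusion_time(mixing_time_ms))
    }
  }
  acquisition_series(dat, dplyr::bind_rows(meta), "dti", config$spacing,
                     extra = list(olefinic_hz = olef_hz))
}

#' Generate the fingerprint series
#'
#' Per-voxel complex time-course from the shared inversion-prepared
#' spoiled-gradient-echo recursion ([mrf_signal()]), as a two-compartment sum
#' of a water pool at the voxel's true water T1 and a fat pool at the fixed
#' fat T1, weighted by the true fat fraction and subject to the local B1+
#' field. The fat pool carries the constant chemical-shift phase
#' `exp(i 2 pi f_fat TE)` accrued at the echo time, which is what lets the
#' dictionary separate fat fraction from T1. Complex Gaussian noise is added.
#'
#' @inheritParams generate_dixon_series
#' @param schedule A [fingerprint_schedule()]; the same schedule must be used
#'   to build the matching dictionary.
#' @return An [acquisition_series()] with complex data, one volume per pulse.
#' @export
generate_fingerprint_series <- function(config,
                                        truth = phantom_ground_truth(config),
                                        schedule = fingerprint_schedule()) {
  if (length(schedule$flip_deg) < 1)
    stop("empty fingerprint schedule", call. = FALSE)
  fr <- phantom_fractions(truth)
  cs <- config$constants
  b1 <- truth$b1[fr$idx]
  fat_phase <- exp(2i * pi * ppm_to_hz(cs$fat_ppm, cs$f0_mhz) *
                     schedule$te_ms / 1000)
  sw <- mrf_signal(truth$t1w[fr$idx], b1, schedule)
  sf <- mrf_signal(rep(cs$fat_t1_ms, length(fr$idx)), b1, schedule)
  sig <- (1 - fr$ffrac) * sw + fr$ffrac * fat_phase * sf
  n <- length(schedule$flip_deg)
  d <- c(config$nx, config$ny, config$nz, n)
  dat <- array(complex(real = 0), d)
  nvox <- prod(d[1:3])
  for (k in seq_len(n)) {
    vol <- complex(real = rep(0, nvox))
    vol[fr$idx] <- sig[, k]
    if (config$sigma > 0)
      vol <- vol + with_seed(config$seed + 404 + k,
                             complex_noise(nvox, config$sigma))
    dat[, , , k] <- vol
  }
  acquisition_series(dat, tibble::tibble(volume = seq_len(n),
                                         flip_deg = schedule$flip_deg,
                                         tr_ms = schedule$tr_ms),
                     "fingerprint", config$spacing,
                     extra = list(schedule = schedule))
}

#' Generate a single-voxel proton spectrum
#'
#' Lorentzian water peak at 4.7 ppm plus a carnosine C2H peak at the
#' pH-dependent chemical shift given by the Henderson-Hasselbalch calibration
#' ([carnosine_shift()]). The carnosine amplitude scales with the voxel's
#' muscle (water) fraction, so its SNR falls as fat fraction rises. Complex
#' Gaussian spectral noise of SD `config$sigma` is added.
#'
#' @inheritParams generate_dixon_series
#' @param muscle,side Muscle code and side selecting the voxel's true pH and
#'   FF from the layout.
#' @param cal A [ph_calibration()].
#' @param resolution_ppm Spectral resolution (ppm per point).
#' @param range_ppm Frequency axis range (ppm).
#' @return An [mrs_spectrum()].
#' @export
generate_spectrum <- function(config, muscle = "GM", side = "R",
                              cal = ph_calibration(),
                              resolution_ppm = 0.002,
                              range_ppm = c(3.5, 9.5),
                              truth = NULL) {
  row <- config$muscles[config$muscles$code == muscle &
                          config$muscles$side == side, ]
  if (nrow(row) != 1)
    stop("muscle/side not found in layout", call. = FALSE)
  if (range_ppm[1] > 4 || range_ppm[2] < 9)
    stop("spectral axis must cover 4-9 ppm", call. = FALSE)
  ppm <- seq(range_ppm[1], range_ppm[2], by = resolution_ppm)
  delta <- carnosine_shift(row$ph, cal)
  lorentz <- function(x0, w) w^2 / ((ppm - x0)^2 + w^2)
  car_amp <- 1.5 * (1 - row$ff / 100)
  sig <- 50 * lorentz(4.70, 0.035) + car_amp * lorentz(delta, 0.020)
  sig <- complex(real = sig)
  if (config$sigma > 0)
    sig <- sig + with_seed(config$seed + 505,
                           complex_noise(length(ppm), config$sigma))
  mrs_spectrum(ppm, sig, f0_mhz = config$constants$f0_mhz)
}
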