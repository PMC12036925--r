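#' Default muscle layout for the synthetic lower-limb phantom
#'
#' Eight elliptical-cylinder muscles (four per side, mirrored left/right) with
#' per-muscle ground-truth parameters spanning the range seen in fatty
#' infiltrated muscle: fat fraction 2-60 %, water T2 28-45 ms, water T1
#' 1000-1400 ms, mean diffusivity 1.4-1.8 um^2/ms, fractional anisotropy
#' 0.21-0.32, resting intramuscular pH near 7.05. Centres and radii are in
#' voxel units of the default 64 x 64 grid; the principal diffusion axis is
#' tilted from the slice normal by `axis_theta_deg` at azimuth
#' `axis_phi_deg`, mimicking muscle fibres running along the limb.
#'
#' @return A tibble with one row per muscle.
#' @export
default_muscle_layout <- function() {
  one_side <- tibble::tibble(
    code  = c("TA", "SOL", "GM", "PER"),
    compartment = "leg",
    cy    = c(9, 25, 41, 57),
    ff    = c(2, 10, 30, 60),
    t2w_ms = c(28, 32, 38, 45),
    t1w_ms = c(1000, 1200, 1400, 1100),
    t2star_ms = c(25, 30, 28, 22),
    lambda1 = c(2.05, 1.85, 2.30, 2.20),
    lambda2 = c(1.55, 1.35, 1.65, 1.40),
    lambda3 = c(1.35, 1.00, 1.45, 1.20),
    axis_theta_deg = c(0, 8, 12, 15),
    axis_phi_deg   = c(0, 30, 120, 250),
    ph    = c(7.00, 7.05, 7.10, 7.15)
  )
  dplyr::bind_rows(
    dplyr::mutate(one_side, side = "L", cx = 16),
    dplyr::mutate(one_side, side = "R", cx = 48)
  ) |>
    dplyr::mutate(label = dplyr::row_number(), rx = 10, ry = 7,
                  name = .data$code, .before = 1) |>
    dplyr::relocate("label", "code", "name", "side", "compartment")
}

#' Configuration of the synthetic lower-limb phantom
#'
#' Defines the image grid, the muscle layout with per-muscle truth, the smooth
#' transmit-field (B1+) and off-resonance (psi) field models, the noise level
#' and the RNG seed. Regenerating any series from the same configuration and
#' seed reproduces it bit for bit.
#'
#' @param nx,ny,nz Grid size in voxels.
#' @param spacing Voxel spacing in mm.
#' @param muscles Muscle layout tibble as returned by
#'   [default_muscle_layout()]; per-muscle columns are the ground truth.
#' @param b1_range Range of the smooth multiplicative B1+ field as a fraction
#'   of the nominal flip angle.
#' @param psi_amp_hz Amplitude of the smooth off-resonance field (Hz); the
#'   realized field spans `[-psi_amp_hz, psi_amp_hz]`.
#' @param sigma Noise standard deviation per complex channel, in units of the
#'   unit muscle signal (Rician noise arises when magnitudes are formed).
#'   `sigma = 0.025` corresponds to SNR 40 in muscle.
#' @param seed Integer RNG seed.
#' @param dixon_te_ms Dixon echo times (ms), strictly increasing.
#' @param mse_te_ms Multi-echo spin-echo times (ms); default 17 echoes at
#'   multiples of 9.5 ms.
#' @param dti_bval b-value of the diffusion acquisition (s/mm^2).
#' @param dti_shifts_ms DOFS readout shifts (ms).
#' @param olefinic_scale Olefinic fat fraction in the diffusion acquisition as
#'   a multiple of the muscle fat fraction (SPAIR removes aliphatic fat; a
#'   fraction proportional to total fat remains as olefinic signal).
#' @param constants Shared model constants, see [qmri_constants()].
#' @return An object of class `phantom_config`.
#' @export
phantom_config <- function(nx = 64, ny = 64, nz = 5, spacing = c(1, 1, 5),
                           muscles = default_muscle_layout(),
                           b1_range = c(0.7, 1.3), psi_amp_hz = 50,
                           sigma = 0.025, seed = 1,
                           dixon_te_ms = c(2.75, 3.95, 5.15),
                           mse_te_ms = (1:17) * 9.5,
                           dti_bval = 400,
                           dti_shifts_ms = c(1.1, 3.3, 5.5, 7.8, 10.0, 12.2),
                           olefinic_scale = 0.25,
                           constants = qmri_constants()) {
  muscles <- tibble::as_tibble(muscles)
  stopifnot(nx > 0, ny > 0, nz > 0, length(spacing) == 3, all(spacing > 0))
  if (anyDuplicated(muscles$label)) stop("muscle labels must be unique", call. = FALSE)
  if (any(muscles$ff < 0 | muscles$ff > 100))
    stop("ff must lie in [0, 100]", call. = FALSE)
  lam <- as.matrix(muscles[, c("lambda1", "lambda2", "lambda3")])
  if (any(lam <= 0)) stop("tensor eigenvalues must be positive", call. = FALSE)
  if (any(lam[, 1] < lam[, 2] | lam[, 2] < lam[, 3]))
    stop("tensor eigenvalues must be sorted descending", call. = FALSE)
  if (any(b1_range <= 0)) stop("B1 field must be positive", call. = FALSE)
  if (sigma < 0) stop("sigma must be >= 0", call. = FALSE)
  if (any(diff(dixon_te_ms) <= 0))
    stop("Dixon echo times must be strictly increasing", call. = FALSE)
  structure(
    list(nx = nx, ny = ny, nz = nz, spacing = as.numeric(spacing),
         muscles = muscles, b1_range = sort(as.numeric(b1_range)),
         psi_amp_hz = psi_amp_hz, sigma = sigma, seed = as.integer(seed),
         dixon_te_ms = dixon_te_ms, mse_te_ms = mse_te_ms,
         dti_bval = dti_bval, dti_shifts_ms = dti_shifts_ms,
         olefinic_scale = olefinic_scale, constants = constants),
    class = "phantom_config")
}

#' @export
print.phantom_config <- function(x, ...) {
  cat(sprintf("<phantom_config> %d x %d x %d, %d muscles, sigma = %g, seed = %d\n",
              x$nx, x$ny, x$nz, nrow(x$muscles), x$sigma, x$seed))
  invisible(x)
}

# Smooth in-plane polynomial field scaled exactly to [lo, hi]; deterministic.
smooth_field <- function(nx, ny, nz, lo, hi, flavour = c("b1", "psi")) {
  flavour <- match.arg(flavour)
  u <- matrix(rep(seq(-1, 1, length.out = nx), ny), nx, ny)
  v <- matrix(rep(seq(-1, 1, length.out = ny), each = nx), nx, ny)
  raw <- switch(flavour,
                b1  = 0.6 * u + 0.4 * v + 0.35 * (u^2 - v^2),
                psi = 0.5 * u - 0.8 * v + 0.4 * u * v)
  raw <- (raw - min(raw)) / (max(raw) - min(raw))   # -> [0, 1]
  slice <- lo + raw * (hi - lo)
  array(rep(slice, nz), c(nx, ny, nz))
}

rotation_from_z <- function(theta_deg, phi_deg) {
  th <- theta_deg * pi / 180; ph <- phi_deg * pi / 180
  axis <- c(sin(th) * cos(ph), sin(th) * sin(ph), cos(th))
  # orthonormal frame with first vector = principal axis
  ref <- if (abs(axis[3]) < 0.9) c(0, 0, 1) else c(1, 0, 0)
  e2 <- ref - sum(ref * axis) * axis; e2 <- e2 / sqrt(sum(e2^2))
  e3 <- c(axis[2] * e2[3] - axis[3] * e2[2],
          axis[3] * e2[1] - axis[1] * e2[3],
          axis[1] * e2[2] - axis[2] * e2[1])
  cbind(axis, e2, e3)
}

#' Realize the phantom ground truth
#'
#' Rasterizes the muscle layout into an integer label map and per-voxel truth
#' maps (FF, water T2, water T1, pH, the full diffusion tensor) plus the
#' smooth B1+ and off-resonance fields. Purely deterministic given the
#' configuration.
#'
#' @param config A [phantom_config()].
#' @return An object of class `phantom_ground_truth` with elements `labels`
#'   (integer array), `ff`, `t2w`, `t1w`, `t2star`, `ph` (arrays, NA outside
#'   muscle), `tensor` (`[nx,ny,nz,6]` array, order xx yy zz xy xz yz),
#'   `b1`, `psi` (arrays), `truth` (the per-muscle table) and `config`.
#' @export
phantom_ground_truth <- function(config) {
  stopifnot(inherits(config, "phantom_config"))
  nx <- config$nx; ny <- config$ny; nz <- config$nz
  xs <- matrix(rep(seq_len(nx), ny), nx, ny)
  ys <- matrix(rep(seq_len(ny), each = nx), nx, ny)
  lab2d <- matrix(0L, nx, ny)
  for (i in seq_len(nrow(config$muscles))) {
    m <- config$muscles[i, ]
    inside <- ((xs - m$cx) / m$rx)^2 + ((ys - m$cy) / m$ry)^2 <= 1
    if (any(lab2d[inside] != 0L))
      stop("muscle ellipses overlap", call. = FALSE)
    lab2d[inside] <- m$label
  }
  labels <- array(rep(lab2d, nz), c(nx, ny, nz))

  lut <- function(col) {
    v <- rep(NA_real_, max(config$muscles$label))
    v[config$muscles$label] <- config$muscles[[col]]
    out <- array(NA_real_, dim(labels))
    out[labels > 0] <- v[labels[labels > 0]]
    out
  }
  tensor <- array(NA_real_, c(nx, ny, nz, 6))
  for (i in seq_len(nrow(config$muscles))) {
    m <- config$muscles[i, ]
    R <- rotation_from_z(m$axis_theta_deg, m$axis_phi_deg)
    D <- R %*% diag(c(m$lambda1, m$lambda2, m$lambda3)) %*% t(R)
    comp <- c(D[1, 1], D[2, 2], D[3, 3], D[1, 2], D[1, 3], D[2, 3])
    idx <- labels == m$label
    for (k in 1:6) {
      sl <- tensor[, , , k]; sl[idx] <- comp[k]; tensor[, , , k] <- sl
    }
  }
  structure(
    list(labels = labels,
         ff = lut("ff"), t2w = lut("t2w_ms"), t1w = lut("t1w_ms"),
         t2star = lut("t2star_ms"), ph = lut("ph"), tensor = tensor,
         b1  = smooth_field(nx, ny, nz, config$b1_range[1], config$b1_range[2], "b1"),
         psi = smooth_field(nx, ny, nz, -config$psi_amp_hz, config$psi_amp_hz, "psi"),
         truth = config$muscles, seed = config$seed, config = config),
    class = "phantom_ground_truth")
}

#' @export
print.phantom_ground_truth <- function(x, ...) {
  cat(sprintf("<phantom_ground_truth> %d muscles, %d muscle voxels of %d\n",
              nrow(x$truth), sum(x$labels > 0), length(x$labels)))
  invisible(x)
}

# Evaluate `code` under a deterministic RNG stream derived from `seed`,
# restoring the caller's RNG state afterwards.
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, globalenv())
    else if (exists(".Random.seed", globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

complex_noise <- function(n, sigma) {
  complex(real = rnorm(n, sd = sigma), imaginary = rnorm(n, sd = sigma))
}
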