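#' Diffusion time from the stimulated-echo mixing time
#'
#' The sequence timing adds a fixed 16.3 ms to the mixing time: mixing times
#' of 100/200/300/400 ms give diffusion times of 116.3/216.3/316.3/416.3 ms.
#'
#' @param mixing_time_ms Mixing time (ms), non-negative.
#' @return Diffusion time (ms).
#' @export
compute_diffusion_time <- function(mixing_time_ms) {
  if (any(mixing_time_ms < 0)) stop("mixing time must be >= 0", call. = FALSE)
  mixing_time_ms + 16.3
}

#' b-matrix rows from b-values and gradient directions
#'
#' Returns the six independent components `(Bxx, Byy, Bzz, Bxy, Bxz, Byz)` of
#' `B = b g g'` per volume; the tensor fit applies them exactly through
#' `b:D = Bxx Dxx + ... + 2 Bxy Dxy + ...`. With `b_imaging > 0` an idealized
#' imaging-gradient contribution along `imaging_dir` is added, including the
#' cross terms `overlap sqrt(b b_img) (g gi' + gi g')` of two overlapping
#' trapezoidal lobes, which is how imaging gradients perturb the effective
#' b-matrix.
#'
#' @param bval Numeric vector of b-values (s/mm^2).
#' @param bvec Matrix of unit directions, one row per volume.
#' @param b_imaging Scalar imaging-gradient b contribution (s/mm^2).
#' @param imaging_dir Unit direction of the imaging gradient.
#' @param overlap Temporal overlap factor in `[0, 1]` for the cross term.
#' @return Matrix `length(bval) x 6`.
#' @export
compute_bmatrix <- function(bval, bvec, b_imaging = 0,
                            imaging_dir = c(0, 1, 0), overlap = 1) {
  bvec <- rbind(bvec)
  stopifnot(length(bval) == nrow(bvec), ncol(bvec) == 3)
  gi <- imaging_dir / sqrt(sum(imaging_dir^2))
  t(vapply(seq_along(bval), function(k) {
    g <- bvec[k, ]
    B <- bval[k] * tcrossprod(g)
    if (b_imaging > 0) {
      B <- B + b_imaging * tcrossprod(gi) +
        overlap * sqrt(bval[k] * b_imaging) * (tcrossprod(g, gi) +
                                                 tcrossprod(gi, g))
    }
    c(B[1, 1], B[2, 2], B[3, 3], B[1, 2], B[1, 3], B[2, 3])
  }, numeric(6)))
}

#' Local-PCA noise estimation and SNR map
#'
#' The noise standard deviation is estimated from overlapping local patches of
#' the b = 0 volumes by principal component analysis of the patch-by-volume
#' matrix: the eigenvalue spectrum is split into signal and noise components
#' with a Marchenko-Pastur-style criterion and sigma^2 is the mean of the
#' noise eigenvalues. The SNR map is `mean(b0 signal) / sigma` per voxel
#' (capped at 1e6 so a noise-free input is "above any threshold" rather than
#' infinite).
#'
#' @param b0 4D array `[nx, ny, nz, m]` of b = 0 magnitude volumes (m >= 1),
#'   or an [acquisition_series()] from which the b = 0 volumes are taken
#'   (magnitudes of all `bval == 0` volumes across readout shifts).
#' @param patch Patch half-width in-plane (patch is `(2p+1) x (2p+1) x 1`).
#' @return A list with `sigma` and `snr` (3D arrays).
#' @export
estimate_noise_and_snr <- function(b0, patch = 2L) {
  if (inherits(b0, "acquisition_series")) {
    sel <- which(b0$meta$bval == 0)
    if (!length(sel)) stop("series has no b = 0 volume", call. = FALSE)
    b0 <- Mod(b0$data[, , , sel, drop = FALSE])
  }
  stopifnot(length(dim(b0)) == 4)
  d <- dim(b0); m <- d[4]
  if (2 * patch + 1 > d[1] || 2 * patch + 1 > d[2])
    stop("patch larger than image", call. = FALSE)
  sigma <- array(0, d[1:3])
  npx <- (2 * patch + 1)^2
  for (z in seq_len(d[3])) {
    sl <- b0[, , z, , drop = FALSE]
    for (y in seq_len(d[2])) {
      ys <- pmin(pmax((y - patch):(y + patch), 1L), d[2])
      for (x in seq_len(d[1])) {
        xs <- pmin(pmax((x - patch):(x + patch), 1L), d[1])
        X <- matrix(sl[xs, ys, 1, ], npx, m)
        sigma[x, y, z] <- mppca_sigma(X)
      }
    }
  }
  mean_b0 <- apply(b0, 1:3, mean)
  snr <- ifelse(sigma > 0, mean_b0 / sigma, 1e6)
  snr <- pmin(snr, 1e6)
  list(sigma = sigma, snr = array(snr, d[1:3]))
}

# Marchenko-Pastur split of the eigenvalue spectrum of one patch matrix
# (npx x m): the smallest eigenvalues whose spread is consistent with pure
# noise define sigma^2.
mppca_sigma <- function(X) {
  npx <- nrow(X); m <- ncol(X)
  if (m == 1) {
    # single volume: fall back to local SD around the patch mean
    return(sd(X))
  }
  lam <- sort(eigen(crossprod(X) / npx, symmetric = TRUE,
                    only.values = TRUE)$values, decreasing = TRUE)
  lam[lam < 0] <- 0
  for (p in 0:(m - 1)) {
    tail_lam <- lam[(p + 1):m]
    sig1 <- mean(tail_lam)
    gamma <- (m - p) / npx
    sig2 <- (lam[p + 1] - lam[m]) / (4 * sqrt(gamma))
    if (sig2 <= sig1) return(sqrt(max(sig1, 0)))
  }
  sqrt(max(lam[m], 0))
}

#' Dixon-based olefinic fat-water decomposition over readout shifts
#'
#' Per voxel, least-squares fit of the complex signal across the readout
#' shifts `t_s` to
#' `S(t_s) = (W + F exp(i 2 pi f_olef t_s)) exp(i (phi0 + 2 pi psi t_s))`,
#' where `F` is the olefinic fat left unsuppressed by SPAIR (about +0.6 ppm
#' from water). For fixed `psi` the complex amplitudes solve a 2 x 2 linear
#' system, so the fit is a 1-D search over `psi` with parabolic sub-grid
#' refinement; `psi` is the field-rate estimate.
#'
#' @param shifted Complex array whose last dimension indexes readout shifts
#'   (`[..., n_shifts]`), or a matrix voxels x shifts.
#' @param shifts_ms Readout shifts (ms), at least 3.
#' @param olefinic_hz Olefinic offset from water (Hz); default from the
#'   shared constants.
#' @param psi_step_hz Field-rate grid step (Hz).
#' @return An object of class `dofs_result` with (same spatial shape as the
#'   input) `water`, `fat` magnitudes, `olefinic_ff` (percent; a
#'   [quantitative_map()] when input is an array, masked where total signal is
#'   zero), `psi` (Hz).
#' @export
dofs_decompose <- function(shifted, shifts_ms,
                           olefinic_hz = ppm_to_hz(qmri_constants()$olefinic_ppm),
                           psi_step_hz = 5) {
  if (length(shifts_ms) < 3)
    stop("at least 3 readout shifts are required for identifiability",
         call. = FALSE)
  dims <- dim(shifted)
  spatial <- NULL
  if (length(dims) > 2) {
    spatial <- dims[-length(dims)]
    shifted <- matrix(shifted, ncol = dims[length(dims)])
  }
  stopifnot(ncol(shifted) == length(shifts_ms))
  S <- t(shifted)                       # shifts x voxels
  n <- ncol(S); ns <- length(shifts_ms)
  ts <- shifts_ms / 1000
  v <- exp(2i * pi * olefinic_hz * ts)
  g <- sum(v)                           # <1, v> Gram off-diagonal
  det <- ns^2 - Mod(g)^2
  ssY <- colSums(Mod(S)^2)
  dts <- mean(diff(ts))
  psi_max <- 1 / (2 * dts)
  psi_grid <- seq(-psi_max, psi_max, by = psi_step_hz)

  amp_at_psi <- function(psi_vec) {
    # psi per voxel; returns A (water), C (fat) complex amplitudes + resid
    P <- exp(-2i * pi * outer(ts, psi_vec))
    Y <- P * S
    h1 <- colSums(Y)
    h2 <- colSums(Conj(v) * Y)
    A <- (ns * h1 - g * h2) / det
    C <- (ns * h2 - Conj(g) * h1) / det
    resid <- ssY - Re(Conj(A) * h1 + Conj(C) * h2)
    list(A = A, C = C, resid = resid)
  }

  # The two-component model is swap-degenerate: (W, F, psi) and
  # (F, W, psi + f_olef) fit equally well. Olefinic fat is by construction
  # the minor component after SPAIR, so solutions with F > W are rejected
  # during the search, which pins the physical branch.
  Rmat <- matrix(Inf, length(psi_grid), n)
  Rfree <- matrix(Inf, length(psi_grid), n)
  for (j in seq_along(psi_grid)) {
    a <- amp_at_psi(rep(psi_grid[j], n))
    r <- a$resid
    Rfree[j, ] <- r
    r[Mod(a$C) > Mod(a$A)] <- Inf
    Rmat[j, ] <- r
  }
  # voxels where every candidate was rejected fall back to the
  # unconstrained search
  none_ok <- !apply(is.finite(Rmat), 2, any)
  if (any(none_ok)) Rmat[, none_ok] <- Rfree[, none_ok]
  j_best <- max.col(-t(Rmat))
  # shrinking-step parabolic refinement of psi to convergence (the residual
  # is smooth in psi; noiseless voxels reach the exact minimum)
  psi <- psi_grid[j_best]
  r0 <- amp_at_psi(psi)$resid
  d_psi <- rep(psi_step_hz / 2, n)
  for (it in 1:18) {
    rm1 <- amp_at_psi(psi - d_psi)$resid
    rp1 <- amp_at_psi(psi + d_psi)$resid
    den <- rm1 - 2 * r0 + rp1
    step <- ifelse(den > 0, 0.5 * (rm1 - rp1) / den, 0)
    cand <- psi + pmin(pmax(step, -1), 1) * d_psi
    rc <- amp_at_psi(cand)$resid
    take <- rc < r0
    psi[take] <- cand[take]; r0[take] <- rc[take]
    d_psi <- d_psi / 2
  }
  fin <- amp_at_psi(psi)
  W <- Mod(fin$A); F <- Mod(fin$C)
  tot <- W + F
  off <- ifelse(tot > 0, F / tot * 100, NA_real_)
  zero <- ssY == 0
  W[zero] <- NA_real_; F[zero] <- NA_real_; psi[zero] <- NA_real_

  shape <- function(x) if (is.null(spatial)) x else array(x, spatial)
  offm <- shape(off)
  res <- list(water = shape(W), fat = shape(F), psi = shape(psi))
  if (!is.null(spatial) && length(spatial) == 3) {
    res$olefinic_ff <- quantitative_map(offm, parameter = "olefinic_ff",
                                        unit = "%")
  } else res$olefinic_ff <- offm
  structure(res, class = "dofs_result")
}

#' Nonlinear least-squares diffusion tensor fit for one voxel
#'
#' Fits `S = S0 exp(-b:D)` with symmetric `D` (um^2/ms) to the signals of one
#' voxel given per-volume b-matrices. A log-linear solve initializes
#' Gauss-Newton iterations on the exponential model. Eigenvalues are sorted
#' descending; negative eigenvalues are clamped to zero and flagged.
#'
#' @param signals Numeric vector of per-volume signals (>= 7, including
#'   b = 0).
#' @param bmatrix Matrix `nvol x 6` of b-matrix components (see
#'   [compute_bmatrix()]), in s/mm^2.
#' @return An object of class `tensor_fit`: `tensor` (3 x 3), `lambda`
#'   (descending), `md`, `fa`, `s0`, `resid`, `clamped`.
#' @export
fit_tensor <- function(signals, bmatrix) {
  bmatrix <- rbind(bmatrix)
  stopifnot(length(signals) == nrow(bmatrix), ncol(bmatrix) == 6)
  X <- cbind(1, -bmatrix %*% diag(c(1, 1, 1, 2, 2, 2)) * 1e-3)
  if (qr(X)$rank < 7)
    stop("rank-deficient diffusion design", call. = FALSE)
  if (any(signals <= 0))
    stop("non-positive signal cannot be tensor-fitted", call. = FALSE)
  beta <- qr.solve(X, log(signals))
  # Gauss-Newton on the exponential model
  for (it in 1:25) {
    eta <- as.numeric(X %*% beta)
    f <- exp(eta)
    r <- signals - f
    J <- f * X
    step <- tryCatch(qr.solve(J, r), error = function(e) rep(0, 7))
    beta <- beta + step
    if (sqrt(sum(step^2)) < 1e-12) break
  }
  eta <- as.numeric(X %*% beta)
  resid <- sqrt(sum((signals - exp(eta))^2))
  D <- matrix(c(beta[2], beta[5], beta[6],
                beta[5], beta[3], beta[7],
                beta[6], beta[7], beta[4]), 3, 3)
  tensor_metrics(D, exp(beta[1]), resid)
}

tensor_metrics <- function(D, s0, resid) {
  e <- eigen(D, symmetric = TRUE)
  lam <- sort(e$values, decreasing = TRUE)
  clamped <- any(lam < 0)
  lam <- pmax(lam, 0)
  md <- mean(lam)
  ss <- sum((lam - md)^2); s2 <- sum(lam^2)
  fa <- if (s2 > 0) sqrt(1.5 * ss / s2) else 0
  structure(list(tensor = D, lambda = lam, md = md, fa = fa, s0 = s0,
                 resid = resid, clamped = clamped,
                 axis = e$vectors[, which.max(e$values)]),
            class = "tensor_fit")
}

#' @export
print.tensor_fit <- function(x, ...) {
  cat(sprintf("<tensor_fit> MD = %.3f um^2/ms, FA = %.3f, lambda = %s%s\n",
              x$md, x$fa, paste(sprintf("%.3f", x$lambda), collapse = "/"),
              if (x$clamped) " [clamped]" else ""))
  invisible(x)
}

#' Voxelwise tensor fit of DOFS water signals
#'
#' @param water Matrix voxels x volumes of (positive) water signals, or a 4D
#'   array.
#' @param bmatrix Per-volume b-matrix (`nvol x 6`).
#' @param mask Optional logical selection of voxels (for array input).
#' @return A list of class `tensor_map_result`: [quantitative_map()]s `md`,
#'   `fa`, `lambda1`..`lambda3`, plus `s0` and `resid` arrays.
#' @export
fit_tensor_map <- function(water, bmatrix, mask = NULL) {
  d <- dim(water)
  spatial <- d[-length(d)]
  Y <- matrix(water, ncol = d[length(d)])
  if (is.null(mask)) mask <- array(rowSums(is.na(Y) | Y <= 0) == 0, spatial)
  vox <- which(mask & array(rowSums(is.na(Y) | Y <= 0) == 0, spatial))
  out <- matrix(NA_real_, length(vox), 7)  # md fa l1 l2 l3 s0 resid
  for (i in seq_along(vox)) {
    ft <- fit_tensor(Y[vox[i], ], bmatrix)
    out[i, ] <- c(ft$md, ft$fa, ft$lambda, ft$s0, ft$resid)
  }
  to_map <- function(col, name, unit) {
    a <- array(NA_real_, spatial); a[vox] <- out[, col]
    quantitative_map(a, parameter = name, unit = unit)
  }
  arr <- function(col) { a <- array(NA_real_, spatial); a[vox] <- out[, col]; a }
  structure(list(md = to_map(1, "md", "um^2/ms"),
                 fa = to_map(2, "fa", ""),
                 lambda1 = to_map(3, "lambda1", "um^2/ms"),
                 lambda2 = to_map(4, "lambda2", "um^2/ms"),
                 lambda3 = to_map(5, "lambda3", "um^2/ms"),
                 s0 = arr(6), resid = arr(7)),
            class = "tensor_map_result")
}

#' DTI exclusion rules
#'
#' Voxels with SNR below 15 or olefinic fat fraction above 10 % are excluded;
#' muscles with an overall (Dixon) FF above 50 % are excluded from the DTI
#' analysis entirely, as are muscles with fewer than 50 voxels. All
#' thresholds are strict; boundary values are retained. Muscle-level rules
#' dominate voxel-level rules in the ledger.
#'
#' @param snr Voxel SNR value(s).
#' @param olefinic_ff Voxel olefinic FF (%).
#' @param muscle_ff Overall muscle FF (%) (recycled).
#' @param n_voxels Muscle voxel count (recycled).
#' @return Character vector of exclusion codes: `"none"`, `"snr_low"`,
#'   `"olefinic_high"`, `"muscle_ff_high"`, `"too_few_voxels"`.
#' @export
apply_dti_exclusions <- function(snr, olefinic_ff, muscle_ff, n_voxels) {
  n <- max(length(snr), length(olefinic_ff), length(muscle_ff),
           length(n_voxels))
  snr <- rep_len(snr, n); olefinic_ff <- rep_len(olefinic_ff, n)
  muscle_ff <- rep_len(muscle_ff, n); n_voxels <- rep_len(n_voxels, n)
  code <- rep("none", n)
  code[olefinic_ff > 10] <- "olefinic_high"
  code[snr < 15] <- "snr_low"
  code[n_voxels < 50] <- "too_few_voxels"
  code[muscle_ff > 50] <- "muscle_ff_high"
  code
}

#' Full diffusion processing chain for one mixing time
#'
#' Noise/SNR estimation on the b = 0 volumes, olefinic fat-water
#' decomposition per gradient across readout shifts, tensor fit on the water
#' signals, and voxel-level exclusion of low-SNR and olefinic-contaminated
#' voxels from the MD/FA maps.
#'
#' @param series A DOFS diffusion [acquisition_series()] (complex; metadata
#'   columns `bval`, `gx`, `gy`, `gz`, `shift_ms`).
#' @param mask Optional logical array restricting the fit.
#' @param correct_olefinic If `FALSE`, skip the decomposition and use the
#'   first-shift magnitude (olefinic fat included) as the "water" signal —
#'   i.e. process as if no olefinic suppression had been acquired, for
#'   quantifying the bias the correction removes.
#' @param snr Optionally a precomputed SNR array; `NULL` estimates it.
#' @return A list of class `dti_result`: `tensor_maps`
#'   (a `tensor_map_result` with exclusions applied to `md`/`fa`/eigenvalue
#'   maps), `snr`, `sigma`, `olefinic_ff`, `bmatrix`, `diffusion_time_ms`.
#' @export
process_dti_series <- function(series, mask = NULL, correct_olefinic = TRUE,
                               snr = NULL) {
  stopifnot(inherits(series, "acquisition_series"))
  meta <- series$meta
  grads <- dplyr::distinct(meta, .data$bval, .data$gx, .data$gy, .data$gz)
  d <- dim(series$data)[1:3]
  shifts <- sort(unique(meta$shift_ms))
  nois <- estimate_noise_and_snr(series)
  if (is.null(snr)) snr <- nois$snr
  water <- array(NA_real_, c(d, nrow(grads)))
  olef <- NULL
  for (gi in seq_len(nrow(grads))) {
    sel <- which(meta$bval == grads$bval[gi] & meta$gx == grads$gx[gi] &
                   meta$gy == grads$gy[gi] & meta$gz == grads$gz[gi])
    sel <- sel[order(meta$shift_ms[sel])]
    vols <- series$data[, , , sel, drop = FALSE]
    if (correct_olefinic) {
      dr <- dofs_decompose(vols, sort(meta$shift_ms[sel]),
                           olefinic_hz = series$extra$olefinic_hz %||%
                             ppm_to_hz(qmri_constants()$olefinic_ppm))
      water[, , , gi] <- dr$water
      if (grads$bval[gi] == 0) olef <- dr$olefinic_ff
    } else {
      water[, , , gi] <- Mod(vols[, , , 1])
      if (grads$bval[gi] == 0)
        olef <- quantitative_map(array(0, d), parameter = "olefinic_ff",
                                 unit = "%")
    }
  }
  bmat <- compute_bmatrix(grads$bval, as.matrix(grads[, c("gx", "gy", "gz")]))
  tm <- fit_tensor_map(water, bmat, mask = mask)
  bad_snr <- !is.na(snr) & snr < 15
  bad_olef <- !is.na(olef$values) & olef$values > 10
  for (nm in c("md", "fa", "lambda1", "lambda2", "lambda3")) {
    tm[[nm]] <- exclude_voxels(tm[[nm]], bad_snr, "snr_low")
    tm[[nm]] <- exclude_voxels(tm[[nm]], bad_olef, "olefinic_high")
  }
  structure(list(tensor_maps = tm, snr = snr, sigma = nois$sigma,
                 olefinic_ff = olef, bmatrix = bmat,
                 diffusion_time_ms = unique(meta$diffusion_time_ms)),
            class = "dti_result")
}
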