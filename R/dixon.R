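# Separable Gaussian blur of one 2D slice with replicate padding; `weight`
# gives confidence weighting (signal magnitude) so background voxels do not
# drag the field map.
gaussian_blur2d <- function(x, weight = NULL, sd = 3) {
  half <- max(1L, ceiling(3 * sd))
  k <- exp(-(seq(-half, half))^2 / (2 * sd^2)); k <- k / sum(k)
  pad_conv <- function(m) {
    nr <- nrow(m); nc <- ncol(m)
    ri <- pmin(pmax(seq(1 - half, nr + half), 1L), nr)
    ci <- pmin(pmax(seq(1 - half, nc + half), 1L), nc)
    m2 <- m[ri, ]
    m2 <- apply(m2, 2, function(col) stats::filter(col, k, sides = 2))
    m2 <- m2[(half + 1):(half + nr), , drop = FALSE]
    m3 <- m2[, ci, drop = FALSE]
    m3 <- t(apply(m3, 1, function(row) stats::filter(row, k, sides = 2)))
    m3[, (half + 1):(half + nc), drop = FALSE]
  }
  if (is.null(weight)) return(pad_conv(x))
  num <- pad_conv(x * weight)
  den <- pad_conv(weight)
  out <- num / den
  out[!is.finite(out)] <- 0
  out
}

#' Three-point Dixon fat-water separation
#'
#' Per-voxel least-squares fit of the complex three-echo signal to
#' `S(TE) = (W + F exp(i 2 pi f_fat TE)) exp(i 2 pi psi TE) exp(-TE/T2*)`
#' with a single-peak fat spectrum and a single common T2* decay. For fixed
#' `(psi, T2*)` the nonnegative amplitudes `(W, F)` solve a 2 x 2 linear
#' system, so the fit reduces to a search over `(psi, T2*)`. Because the
#' three-echo misfit is bimodal in `psi` (the fat-water swap), the raw
#' per-voxel minimum is regularized by an iterated-conditional-modes pass that
#' pulls each voxel's field-map estimate towards a signal-weighted smooth of
#' its neighbourhood, followed by parabolic sub-grid refinement of `psi` and a
#' fine T2* search.
#'
#' @param series An [acquisition_series()] with exactly 3 complex echo volumes
#'   and `te_ms` metadata; `extra$fat_hz` gives the fat offset (Hz), defaulting
#'   to the shared constants.
#' @param mask Logical array of voxels to fit; default thresholds the mean
#'   echo magnitude. All-zero voxels are masked, never errors.
#' @param psi_step_hz Coarse field-map grid step (Hz); the search window is
#'   `+/- 1/(2 dTE)`.
#' @param t2star_bounds T2* search bounds (ms).
#' @param icm_iter,icm_lambda,icm_sd Field-map regularization: number of ICM
#'   sweeps, penalty weight on the squared deviation from the smoothed field
#'   (per unit relative misfit, per Hz^2), and Gaussian smoothing SD (voxels).
#' @return An object of class `fat_water_result`: arrays `water`, `fat`,
#'   `psi`, `t2star`, `converged`, and `ff` as a [quantitative_map()] (percent,
#'   masked where water + fat is zero).
#' @export
separate_fat_water <- function(series, mask = NULL, psi_step_hz = 10,
                               t2star_bounds = c(5, 100),
                               icm_iter = 4, icm_lambda = 3e-5, icm_sd = 3) {
  stopifnot(inherits(series, "acquisition_series"))
  te <- series$meta$te_ms
  if (length(te) != 3)
    stop("three-point Dixon needs exactly 3 echoes", call. = FALSE)
  fat_hz <- series$extra$fat_hz %||% ppm_to_hz(qmri_constants()$fat_ppm)
  d <- dim(series$data)[1:3]
  S_all <- matrix(series$data, ncol = 3)  # voxels x echoes
  magmean <- rowMeans(Mod(S_all))
  if (is.null(mask)) {
    thr <- 0.1 * stats::quantile(magmean, 0.99)
    mask <- array(magmean > thr, d)
  }
  vox <- which(mask)
  S <- t(S_all[vox, , drop = FALSE])      # 3 x N
  n <- length(vox)
  ssS <- colSums(Mod(S)^2)
  w_mag <- magmean[vox]

  te_s <- te / 1000
  c_fat <- exp(2i * pi * fat_hz * te_s)
  dte <- mean(diff(te_s))
  psi_max <- 1 / (2 * dte)
  psi_grid <- seq(-psi_max, psi_max, by = psi_step_hz)
  t2_coarse <- exp(seq(log(t2star_bounds[1]), log(t2star_bounds[2]),
                       length.out = 8))

  solve_node <- function(psi, t2s, Sdem = NULL) {
    # returns list(W, F, resid) for all voxels at one (psi, T2*) node
    E <- exp(-te / t2s)
    u <- exp(2i * pi * psi * te_s) * E
    v <- c_fat * u
    G11 <- sum(Mod(u)^2); G22 <- G11
    G12 <- sum(E^2 * Re(c_fat))
    h1 <- as.numeric(Re(Conj(u) %*% S))
    h2 <- as.numeric(Re(Conj(v) %*% S))
    det <- G11 * G22 - G12^2
    W <- (G22 * h1 - G12 * h2) / det
    F <- (G11 * h2 - G12 * h1) / det
    bad_w <- W < 0; bad_f <- F < 0
    W[bad_w] <- 0; F[bad_w] <- pmax(h2[bad_w] / G22, 0)
    F[bad_f] <- 0; W[bad_f] <- pmax(h1[bad_f] / G11, 0)
    resid <- ssS - 2 * (W * h1 + F * h2) +
      W^2 * G11 + F^2 * G22 + 2 * W * F * G12
    list(W = W, F = F, resid = resid)
  }

  # coarse residual envelope over T2* for every psi grid node
  n_psi <- length(psi_grid)
  Rmat <- matrix(Inf, n_psi, n)
  for (j in seq_len(n_psi)) {
    best <- rep(Inf, n)
    for (t2s in t2_coarse) {
      r <- solve_node(psi_grid[j], t2s)$resid
      best <- pmin(best, r)
    }
    Rmat[j, ] <- best
  }
  Rnorm <- sweep(Rmat, 2, pmax(ssS, .Machine$double.eps), "/")

  # ICM: pull psi towards a signal-weighted smooth of its neighbourhood
  j_best <- max.col(-t(Rnorm))
  psi_v <- psi_grid[j_best]
  for (it in seq_len(icm_iter)) {
    psi_map <- array(0, d); wt <- array(0, d)
    psi_map[vox] <- psi_v; wt[vox] <- w_mag
    sm <- array(0, d)
    for (z in seq_len(d[3]))
      sm[, , z] <- gaussian_blur2d(psi_map[, , z], wt[, , z], sd = icm_sd)
    target <- sm[vox]
    cost <- Rnorm + icm_lambda * (psi_grid - rep(target, each = n_psi))^2
    dim(cost) <- c(n_psi, n)
    j_best <- max.col(-t(cost))
    psi_v <- psi_grid[j_best]
  }

  # per-voxel nonnegative-amplitude solve and residual for given
  # (psi, T2*) vectors; fully elementwise over voxels
  solve_vox <- function(psi_v, t2_v) {
    E <- exp(-outer(te, 1 / t2_v))               # 3 x n
    Q <- exp(-2i * pi * outer(te_s, psi_v)) * S  # demodulated
    G11 <- colSums(E^2)
    G12 <- colSums(E^2 * Re(c_fat))
    h1 <- colSums(E * Re(Q))
    h2 <- colSums(E * Re(Conj(c_fat) * Q))
    det <- G11^2 - G12^2
    W <- (G11 * h1 - G12 * h2) / det
    F <- (G11 * h2 - G12 * h1) / det
    bad_w <- W < 0; bad_f <- F < 0
    W[bad_w] <- 0; F[bad_w] <- pmax(h2[bad_w] / G11[bad_w], 0)
    F[bad_f] <- 0; W[bad_f] <- pmax(h1[bad_f] / G11[bad_f], 0)
    r <- ssS - 2 * (W * h1 + F * h2) + (W^2 + F^2) * G11 + 2 * W * F * G12
    list(W = W, F = F, resid = r)
  }

  # refinement of (psi, T2*) to convergence: alternating shrinking-step
  # parabolic line searches from the grid solution. The phase (psi) and
  # magnitude (T2*) axes are nearly decoupled, so this converges quickly and
  # reproduces the exact solution on noiseless data.
  psi_v <- psi_grid[j_best]
  t2_coarse2 <- exp(seq(log(t2star_bounds[1]), log(t2star_bounds[2]),
                        length.out = 24))
  best_r <- rep(Inf, n); t2_v <- rep(t2_coarse2[1], n)
  for (t2s in t2_coarse2) {
    r <- solve_vox(psi_v, rep(t2s, n))$resid
    upd <- r < best_r
    best_r[upd] <- r[upd]; t2_v[upd] <- t2s
  }
  r0 <- best_r
  d_psi <- rep(psi_step_hz / 2, n)
  d_log <- rep(0.1, n)
  for (it in 1:18) {
    rm1 <- solve_vox(psi_v - d_psi, t2_v)$resid
    rp1 <- solve_vox(psi_v + d_psi, t2_v)$resid
    den <- rm1 - 2 * r0 + rp1
    step <- ifelse(den > 0, 0.5 * (rm1 - rp1) / den, 0)
    step <- pmin(pmax(step, -1), 1)
    cand <- psi_v + step * d_psi
    rc <- solve_vox(cand, t2_v)$resid
    take <- rc < r0
    psi_v[take] <- cand[take]; r0[take] <- rc[take]
    d_psi <- d_psi / 2

    lm1 <- solve_vox(psi_v, pmax(t2_v * exp(-d_log), t2star_bounds[1]))$resid
    lp1 <- solve_vox(psi_v, pmin(t2_v * exp(d_log), t2star_bounds[2]))$resid
    den <- lm1 - 2 * r0 + lp1
    step <- ifelse(den > 0, 0.5 * (lm1 - lp1) / den, 0)
    step <- pmin(pmax(step, -1), 1)
    cand_t <- pmin(pmax(t2_v * exp(step * d_log), t2star_bounds[1]),
                   t2star_bounds[2])
    rc <- solve_vox(psi_v, cand_t)$resid
    take <- rc < r0
    t2_v[take] <- cand_t[take]; r0[take] <- rc[take]
    d_log <- d_log / 1.6
  }
  fin <- solve_vox(psi_v, t2_v)
  W_v <- fin$W; F_v <- fin$F; best_t <- t2_v

  to_arr <- function(v, fill = NA_real_) {
    a <- array(fill, d); a[vox] <- v; a
  }
  water <- to_arr(W_v, 0); fat <- to_arr(F_v, 0)
  res <- structure(
    list(water = water, fat = fat,
         psi = to_arr(psi_v), t2star = to_arr(best_t),
         converged = array(mask, d),
         ff = compute_ff(water, fat)),
    class = "fat_water_result")
  res$ff$mask <- res$ff$mask & mask
  res$ff$reason[!mask] <- "undefined"
  res
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.fat_water_result <- function(x, ...) {
  cat("<fat_water_result>\n")
  print(x$ff)
  invisible(x)
}

#' Fat-fraction map from water and fat magnitudes
#'
#' `FF = fat / (water + fat) * 100`, masked (undefined) where the denominator
#' is zero so that empty voxels never bias muscle means.
#'
#' @param water,fat Nonnegative magnitude arrays of equal dimension.
#' @return A [quantitative_map()] in percent.
#' @export
compute_ff <- function(water, fat) {
  if (any(water < 0, na.rm = TRUE) || any(fat < 0, na.rm = TRUE))
    stop("magnitudes must be nonnegative", call. = FALSE)
  stopifnot(all(dim(water) == dim(fat)))
  den <- water + fat
  vals <- ifelse(den > 0, fat / den * 100, NA_real_)
  vals <- array(vals, dim(water))
  quantitative_map(vals, parameter = "ff", unit = "%")
}

#' Contractile cross-sectional area
#'
#' `cCSA = (1 - 0.01 FF) * CSA`: the part of the anatomical cross-section not
#' replaced by fat.
#'
#' @param csa Cross-sectional area (mm^2), nonnegative.
#' @param ff Mean fat fraction (percent), in `[0, 100]`.
#' @return cCSA in mm^2 (vectorized).
#' @export
compute_ccsa <- function(csa, ff) {
  if (any(ff < 0 | ff > 100, na.rm = TRUE))
    stop("FF must lie in [0, 100]", call. = FALSE)
  if (any(csa < 0, na.rm = TRUE))
    stop("CSA must be nonnegative", call. = FALSE)
  (1 - 0.01 * ff) * csa
}

#' Per-muscle cross-sectional area from a label map
#'
#' CSA per slice is the in-slice voxel count times the in-plane voxel area;
#' the muscle CSA is the mean over the selected slices.
#'
#' @param labels Integer 3D label array.
#' @param spacing Voxel spacing (mm), first two entries in-plane.
#' @param slices Slice indices to average over (default: all).
#' @param muscle_labels Labels to report (default: all present).
#' @return Tibble with `label`, `csa_mm2`, `n_slices`.
#' @export
compute_csa <- function(labels, spacing, slices = seq_len(dim(labels)[3]),
                        muscle_labels = NULL) {
  stopifnot(length(dim(labels)) == 3, length(spacing) >= 2)
  area <- spacing[1] * spacing[2]
  sub <- labels[, , slices, drop = FALSE]
  if (is.null(muscle_labels))
    muscle_labels <- sort(setdiff(unique(as.integer(sub)), 0L))
  purrr::map_dfr(muscle_labels, function(l) {
    per_slice <- apply(sub, 3, function(sl) sum(sl == l))
    if (all(per_slice == 0))
      warning(sprintf("label %d absent in selected slices", l), call. = FALSE)
    tibble::tibble(label = l, csa_mm2 = mean(per_slice) * area,
                   n_slices = length(slices))
  })
}
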