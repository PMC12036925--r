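# Vectorized tri-exponential fit over columns of Y (echoes x voxels).
# One free water component (A_w, T2w) plus a fat term A_f with two fixed-T2
# components at fixed relative weights; for fixed T2w the amplitudes solve a
# nonnegative 2x2 linear system, so the fit is a 1-D search over T2w.
triexp_fit_matrix <- function(Y, te_ms, constants = qmri_constants(),
                              t2_bounds = c(8, 100), grid_step = 0.5) {
  ne <- length(te_ms); n <- ncol(Y)
  fatvec <- as.numeric(exp(-outer(te_ms, constants$fat_t2_ms, "/")) %*%
                         constants$fat_weights)
  ssY <- colSums(Y^2)
  hf <- as.numeric(fatvec %*% Y)
  Gff <- sum(fatvec^2)
  grid <- seq(t2_bounds[1], t2_bounds[2], by = grid_step)

  solve_t2 <- function(t2w, sel = seq_len(n)) {
    w <- exp(-te_ms / t2w)
    Gww <- sum(w^2); Gwf <- sum(w * fatvec)
    hw <- as.numeric(w %*% Y[, sel, drop = FALSE])
    hfs <- hf[sel]
    det <- Gww * Gff - Gwf^2
    aw <- (Gff * hw - Gwf * hfs) / det
    af <- (Gww * hfs - Gwf * hw) / det
    bad_w <- aw < 0; bad_f <- af < 0
    aw[bad_w] <- 0; af[bad_w] <- pmax(hfs[bad_w] / Gff, 0)
    af[bad_f] <- 0; aw[bad_f] <- pmax(hw[bad_f] / Gww, 0)
    resid <- ssY[sel] - 2 * (aw * hw + af * hfs) +
      aw^2 * Gww + af^2 * Gff + 2 * aw * af * Gwf
    list(aw = aw, af = af, resid = resid)
  }

  best_r <- rep(Inf, n); best_j <- rep(1L, n)
  Rkeep <- matrix(NA_real_, 3, n)  # residuals at j-1, j, j+1 for refinement
  Rgrid <- matrix(Inf, length(grid), n)
  for (j in seq_along(grid)) {
    r <- solve_t2(grid[j])$resid
    Rgrid[j, ] <- r
    upd <- r < best_r
    best_r[upd] <- r[upd]; best_j[upd] <- j
  }
  jj <- pmin(pmax(best_j, 2L), length(grid) - 1L)
  y1 <- Rgrid[cbind(jj - 1L, seq_len(n))]
  y2 <- Rgrid[cbind(jj, seq_len(n))]
  y3 <- Rgrid[cbind(jj + 1L, seq_len(n))]
  denom <- y1 - 2 * y2 + y3
  frac <- ifelse(denom > 0, 0.5 * (y1 - y3) / denom, 0)
  frac <- pmin(pmax(frac, -1), 1)
  t2w <- grid[jj] + frac * grid_step

  aw <- numeric(n); af <- numeric(n); resid <- numeric(n)
  for (t2u in unique(round(t2w, 6))) {
    sel <- which(round(t2w, 6) == t2u)
    s <- solve_t2(t2u, sel)
    aw[sel] <- s$aw; af[sel] <- s$af; resid[sel] <- s$resid
  }
  # accept the parabolic refinement only where it actually lowers the
  # residual; otherwise keep the exact grid minimum (an on-grid optimum must
  # be returned unperturbed)
  revert <- which(resid > best_r)
  for (j in unique(best_j[revert])) {
    sel <- revert[best_j[revert] == j]
    s <- solve_t2(grid[j], sel)
    t2w[sel] <- grid[j]
    aw[sel] <- s$aw; af[sel] <- s$af; resid[sel] <- s$resid
  }
  list(t2w = t2w, aw = aw, af = af, resid = sqrt(pmax(resid, 0)))
}

#' Tri-exponential water T2 fit of one multi-echo spin-echo decay
#'
#' Fits `S(TE) = A_w exp(-TE/T2w) + A_f (p1 exp(-TE/T2f1) + p2 exp(-TE/T2f2))`
#' to a magnitude decay by nonlinear least squares, with the two fat T2
#' constants and their relative weights fixed at the shared model constants
#' and only `(A_w, T2w, A_f)` free; 17 magnitude points cannot stably support
#' more free parameters. The T2w search is a dense grid over
#' `t2_bounds` with parabolic sub-grid refinement, which cannot miss the
#' global minimum of this 1-D profile.
#'
#' @param decay Numeric vector of echo magnitudes.
#' @param te_ms Echo times (ms), strictly increasing, at least 8.
#' @param constants Shared model constants ([qmri_constants()]).
#' @param t2_bounds Search bounds for T2w (ms).
#' @param grid_step Grid step (ms).
#' @return An object of class `t2_fit`: `t2w_ms`, `a_w`, `a_f`, `resid`,
#'   `converged`, `exclusion` (initially `"none"`; see
#'   [apply_t2_exclusions()]). An all-zero decay returns a masked
#'   (non-converged) fit, not an error.
#' @export
fit_triexponential <- function(decay, te_ms, constants = qmri_constants(),
                               t2_bounds = c(8, 100), grid_step = 0.5) {
  if (length(te_ms) < 8) stop("need at least 8 echoes", call. = FALSE)
  if (any(diff(te_ms) <= 0))
    stop("echo times must be strictly increasing", call. = FALSE)
  stopifnot(length(decay) == length(te_ms))
  if (all(decay == 0) || anyNA(decay)) {
    return(structure(list(t2w_ms = NA_real_, a_w = NA_real_, a_f = NA_real_,
                          resid = NA_real_, converged = FALSE,
                          exclusion = "masked"),
                     class = "t2_fit"))
  }
  f <- triexp_fit_matrix(matrix(decay, ncol = 1), te_ms, constants,
                         t2_bounds, grid_step)
  structure(list(t2w_ms = f$t2w, a_w = f$aw, a_f = f$af, resid = f$resid,
                 converged = TRUE, exclusion = "none"),
            class = "t2_fit")
}

#' @export
print.t2_fit <- function(x, ...) {
  cat(sprintf("<t2_fit> T2w = %.2f ms, A_w = %.3g, A_f = %.3g (%s)\n",
              x$t2w_ms, x$a_w, x$a_f, x$exclusion))
  invisible(x)
}

#' Voxelwise water T2 map from a multi-echo spin-echo series
#'
#' Applies the tri-exponential fit of [fit_triexponential()] to every voxel in
#' the mask (default: voxels with non-trivial first-echo signal).
#'
#' The Rician noise floor of late magnitude echoes would otherwise be soaked
#' up by the slow fat component and bias T2w downward in lean muscle; when a
#' noise estimate is available (by default from the background voxels outside
#' the mask, whose Rayleigh mean is `sigma sqrt(pi/2)`), the magnitudes are
#' floor-corrected in quadrature (`sqrt(max(M^2 - 2 sigma^2, 0))`) before
#' fitting.
#'
#' @param series An [acquisition_series()] with magnitude data and `te_ms`.
#' @param mask Optional logical array of voxels to fit.
#' @param rician_sigma Noise SD for the magnitude floor correction; `NULL`
#'   estimates it from the background, 0 disables the correction.
#' @inheritParams fit_triexponential
#' @return A list of class `t2_map_result`: `t2` (a [quantitative_map()] in
#'   ms), `a_w`, `a_f`, `resid` arrays.
#' @export
fit_t2_map <- function(series, mask = NULL, constants = qmri_constants(),
                       t2_bounds = c(8, 100), grid_step = 0.5,
                       rician_sigma = NULL) {
  stopifnot(inherits(series, "acquisition_series"))
  te <- series$meta$te_ms
  d <- dim(series$data)[1:3]
  Y_all <- matrix(series$data, ncol = length(te))
  if (is.null(mask)) {
    thr <- 0.1 * stats::quantile(Y_all[, 1], 0.99)
    mask <- array(Y_all[, 1] > thr, d)
  }
  if (is.null(rician_sigma)) {
    bg <- Y_all[!mask, 1]
    rician_sigma <- if (length(bg)) mean(bg) / sqrt(pi / 2) else 0
  }
  if (rician_sigma > 0)
    Y_all <- sqrt(pmax(Y_all^2 - 2 * rician_sigma^2, 0))
  vox <- which(mask)
  f <- triexp_fit_matrix(t(Y_all[vox, , drop = FALSE]), te, constants,
                         t2_bounds, grid_step)
  to_arr <- function(v) { a <- array(NA_real_, d); a[vox] <- v; a }
  structure(list(
    t2 = quantitative_map(to_arr(f$t2w), parameter = "water_t2", unit = "ms"),
    a_w = to_arr(f$aw), a_f = to_arr(f$af), resid = to_arr(f$resid)),
    class = "t2_map_result")
}

t2_exclusion_code <- function(t2w, b1) {
  # b1 accepted as fraction of nominal or percent
  b1 <- ifelse(!is.na(b1) & b1 > 3, b1 / 100, b1)
  code <- rep("none", length(t2w))
  code[!is.na(b1) & b1 < 0.8] <- "b1_low"
  code[!is.na(b1) & b1 > 1.2] <- "b1_high"
  code[!is.na(t2w) & t2w < 15] <- "t2_low"
  code[!is.na(t2w) & t2w > 70] <- "t2_high"
  code
}

#' Water T2 exclusion rules
#'
#' Voxels with water T2 below 15 ms or above 70 ms, and voxels where the
#' transmit field deviates below 80 % or above 120 % of the prescribed flip
#' angle, are excluded from further analysis. All thresholds are strict
#' inequalities: boundary values are retained. When both a T2 and a B1 rule
#' fire, the T2 code is reported. Applying the rules twice is a no-op.
#'
#' @param x A `t2_fit` or `t2_map_result`.
#' @param b1 B1+ value(s) as fraction of nominal (or percent; values above 3
#'   are interpreted as percent). For a map result, an array.
#' @return The input with exclusion codes set (and, for a map, the excluded
#'   voxels masked in the ledger).
#' @export
apply_t2_exclusions <- function(x, b1) {
  if (inherits(x, "t2_fit")) {
    if (identical(x$exclusion, "masked")) return(x)
    x$exclusion <- t2_exclusion_code(x$t2w_ms, b1)
    return(x)
  }
  if (inherits(x, "t2_map_result")) {
    stopifnot(all(dim(b1) == dim(x$t2$values)))
    code <- t2_exclusion_code(as.numeric(x$t2$values), as.numeric(b1))
    code_arr <- array(code, dim(x$t2$values))
    for (reason in c("b1_low", "b1_high", "t2_low", "t2_high"))
      x$t2 <- exclude_voxels(x$t2, code_arr == reason, reason)
    return(x)
  }
  stop("x must be a t2_fit or t2_map_result", call. = FALSE)
}
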