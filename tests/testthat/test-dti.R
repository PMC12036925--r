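test_that("diffusion time adds the 16.3 ms sequence offset", {
  expect_equal(compute_diffusion_time(100), 116.3)
  expect_equal(compute_diffusion_time(400), 416.3)
  expect_equal(compute_diffusion_time(0), 16.3)
  expect_error(compute_diffusion_time(-1), ">= 0")
})

test_that("b-matrix components reproduce b g g' and imaging cross terms", {
  g <- c(1, 0, 0)
  B <- compute_bmatrix(400, g)
  expect_equal(as.numeric(B), c(400, 0, 0, 0, 0, 0))
  Bi <- compute_bmatrix(400, g, b_imaging = 4, imaging_dir = c(0, 1, 0))
  expect_equal(Bi[1, 1], 400)
  expect_equal(Bi[1, 2], 4)            # imaging gradient along y
  expect_equal(Bi[1, 4], sqrt(400 * 4))  # cross term
})

test_that("an isotropic tensor gives FA = 0 and MD = d", {
  bm <- compute_bmatrix(c(0, rep(400, 6)), rbind(c(0, 0, 0), dti_directions()))
  s <- exp(-rowSums(bm[, 1:3]) * 1.5e-3)
  ft <- fit_tensor(s, bm)
  expect_equal(ft$md, 1.5, tolerance = 1e-9)
  expect_lt(ft$fa, 1e-6)
  expect_equal(ft$lambda, rep(1.5, 3), tolerance = 1e-9)
})

test_that("tensor fit recovers a known eigensystem to high accuracy", {
  R <- muscleqmri:::rotation_from_z(20, 40)
  lam <- c(2.0, 1.0, 1.0)
  D <- R %*% diag(lam) %*% t(R)
  dirs <- rbind(c(0, 0, 0), dti_directions())
  bm <- compute_bmatrix(c(0, rep(400, 6)), dirs)
  quad <- function(g) as.numeric(t(g) %*% D %*% g)
  s <- sapply(seq_len(nrow(dirs)), function(i) {
    g <- dirs[i, ]
    b <- c(0, rep(400, 6))[i]
    0.8 * exp(-b * quad(g) * 1e-3)
  })
  ft <- fit_tensor(s, bm)
  expect_equal(ft$lambda, lam, tolerance = 1e-3)
  expect_equal(ft$fa, fa_closed_form(lam), tolerance = 1e-6)
  expect_equal(ft$fa, 0.4082483, tolerance = 1e-6)
  expect_gt(abs(sum(ft$axis * R[, 1])), cos(1 * pi / 180))  # axis within 1 deg
  expect_equal(ft$s0, 0.8, tolerance = 1e-9)
  expect_error(fit_tensor(s, bm * 0), "rank")
})

test_that("MD and FA are invariant to common signal scaling", {
  bm <- compute_bmatrix(c(0, rep(400, 6)), rbind(c(0, 0, 0), dti_directions()))
  s <- exp(-apply(bm, 1, function(b) sum(b[1:3] * c(2, 1.5, 1.2)) * 1e-3))
  f1 <- fit_tensor(s, bm); f2 <- fit_tensor(5 * s, bm)
  expect_equal(f1$md, f2$md, tolerance = 1e-10)
  expect_equal(f1$fa, f2$fa, tolerance = 1e-10)
})

test_that("local PCA noise estimation recovers sigma and the SNR formula", {
  set.seed(5)
  d <- c(40, 40, 3, 6)
  noise <- rnorm(prod(d), sd = 20)
  est <- estimate_noise_and_snr(array(noise, d))
  expect_gt(length(est$sigma), 1e3)
  expect_lt(abs(median(est$sigma) / sd(noise) - 1), 0.1)
  # magnitude (Rician) background: estimate matches the sample SD of the
  # generated magnitudes
  mags <- Mod(complex(real = rnorm(prod(d), sd = 20),
                      imaginary = rnorm(prod(d), sd = 20)))
  estm <- estimate_noise_and_snr(array(mags, d))
  expect_lt(abs(median(estm$sigma) / sd(mags) - 1), 0.1)
  # constant signal 300 + gaussian sigma 20 -> SNR about 15
  sig <- array(300 + rnorm(prod(d), sd = 20), d)
  est2 <- estimate_noise_and_snr(sig)
  expect_lt(abs(median(est2$snr) / 15 - 1), 0.1)
  # zero noise: SNR capped high
  est3 <- estimate_noise_and_snr(array(300, d))
  expect_true(all(est3$snr >= 1e5))
  expect_error(estimate_noise_and_snr(array(1, c(3, 3, 1, 2)), patch = 5),
               "patch")
})

test_that("DOFS recovers water, olefinic fraction and field rate", {
  shifts <- c(1.1, 3.3, 5.5, 7.8, 10.0, 12.2)
  olef_hz <- 0.6 * 127.73
  ts <- shifts / 1000
  mk <- function(w, f, psi, phi0 = 0.3)
    (w + f * exp(2i * pi * olef_hz * ts)) * exp(1i * (phi0 + 2 * pi * psi * ts))
  # F = 0: olefinic FF = 0, W = magnitude
  r0 <- dofs_decompose(matrix(mk(0.9, 0, 10), 1), shifts, olef_hz)
  expect_lt(abs(r0$olefinic_ff), 1e-6)
  expect_equal(as.numeric(r0$water), 0.9, tolerance = 1e-8)
  # zero signal is masked
  rz <- dofs_decompose(matrix(0i, 1, 6), shifts, olef_hz)
  expect_true(is.na(rz$water))
  # W = 0.9, F = 0.1, psi = 20 Hz vs a brute-force grid oracle
  s <- mk(0.9, 0.1, 20)
  r <- dofs_decompose(matrix(s, 1), shifts, olef_hz)
  oracle <- local({
    best <- Inf; bf <- NA
    for (psi in seq(-40, 40, 0.5)) for (f in seq(0, 0.3, 0.005)) {
      for (w in seq(0.7, 1.1, 0.005)) {
        model0 <- (w + f * exp(2i * pi * olef_hz * ts)) *
          exp(2i * pi * psi * ts)
        # optimal global phase in closed form
        ip <- sum(Conj(model0) * s)
        r2 <- sum(Mod(s)^2) + sum(Mod(model0)^2) - 2 * Mod(ip)
        if (r2 < best) { best <- r2; bf <- f / (w + f) * 100 }
      }
    }
    bf
  })
  expect_lt(abs(r$olefinic_ff - oracle), 0.5)
  expect_lt(abs(as.numeric(r$psi) - 20), 0.5)
  expect_error(dofs_decompose(matrix(s[1:2], 1), shifts[1:2], olef_hz),
               "3 readout shifts")
})

test_that("DTI exclusion rules are strict and muscle rules dominate", {
  expect_equal(apply_dti_exclusions(14.9, 0, 10, 500), "snr_low")
  expect_equal(apply_dti_exclusions(50, 10.1, 10, 500), "olefinic_high")
  expect_equal(apply_dti_exclusions(50, 0, 55, 500), "muscle_ff_high")
  expect_equal(apply_dti_exclusions(14, 11, 55, 20), "muscle_ff_high")
  expect_equal(apply_dti_exclusions(50, 0, 10, 49), "too_few_voxels")
  expect_equal(apply_dti_exclusions(15, 10, 50, 50), "none")
})

test_that("the exclusion ledger of a DTI run conserves voxel counts", {
  cfg <- tiny_config(sigma = 0.025, seed = 17)
  tr <- phantom_ground_truth(cfg)
  res <- process_dti_series(generate_dti_series(cfg, 100, tr),
                            mask = tr$labels > 0)
  led <- map_ledger(res$tensor_maps$md)
  expect_equal(sum(led$voxels), length(res$tensor_maps$md$values))
})
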