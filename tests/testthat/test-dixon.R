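test_that("compute_ff implements the printed formula and masks zero voxels", {
  w <- array(c(75, 0, 1), c(3, 1, 1))
  f <- array(c(25, 0, 3), c(3, 1, 1))
  m <- compute_ff(w, f)
  expect_equal(m$values[1, 1, 1], 25)
  expect_equal(m$values[3, 1, 1], 75)
  expect_false(m$mask[2, 1, 1])
  expect_equal(m$reason[2, 1, 1], "undefined")
  expect_error(compute_ff(-w, f), "nonnegative")
})

test_that("compute_ccsa follows (1 - 0.01 FF) * CSA", {
  expect_equal(compute_ccsa(1000, 0), 1000)
  expect_equal(compute_ccsa(1000, 100), 0)
  expect_equal(compute_ccsa(1000, 30), 700)
  expect_error(compute_ccsa(1000, 130), "FF")
  expect_error(compute_ccsa(-5, 10), "CSA")
})

test_that("compute_csa counts voxels times in-plane area", {
  lab <- array(0L, c(20, 20, 2))
  lab[1:10, 1:10, ] <- 1L     # 100 voxels per slice
  expect_equal(compute_csa(lab, c(1, 1, 5))$csa_mm2, 100)
  expect_equal(compute_csa(lab, c(1.4, 1.4, 5))$csa_mm2, 196,
               tolerance = 1e-12)
  # multi-slice with unequal counts: mean over slices
  lab[1:10, 1:5, 2] <- 0L
  expect_equal(compute_csa(lab, c(1, 1, 5))$csa_mm2, mean(c(100, 50)))
  expect_warning(compute_csa(lab, c(1, 1, 5), muscle_labels = 7L), "absent")
})

test_that("noiseless pure-water and pure-fat voxels separate exactly", {
  mus <- default_muscle_layout()
  mus$ff <- rep(c(0, 100), 4)
  cfg <- tiny_config(sigma = 0, muscles = mus)
  tr <- phantom_ground_truth(cfg)
  fw <- separate_fat_water(generate_dixon_series(cfg, tr),
                           mask = tr$labels > 0)
  expect_lt(max(abs(fw$ff$values[tr$labels == 1] - 0)), 1e-6)
  expect_lt(max(abs(fw$ff$values[tr$labels == 2] - 100)), 1e-6)
})

test_that("separate_fat_water recovers FF, psi and handles degenerate input", {
  cfg <- tiny_config(sigma = 0, seed = 4)
  tr <- phantom_ground_truth(cfg)
  ser <- generate_dixon_series(cfg, tr)
  expect_error(separate_fat_water(
    acquisition_series(ser$data[, , , 1:2, drop = FALSE], ser$meta[1:2, ],
                       "dixon")), "3 echoes")
  fw <- separate_fat_water(ser, mask = tr$labels > 0)
  err <- abs(fw$ff$values - tr$ff)[tr$labels > 0]
  expect_lt(median(err), 1)
  expect_equal(mean(err > 50), 0)
  psi_err <- abs(fw$psi - tr$psi)[tr$labels > 0]
  expect_lt(median(psi_err), 1)
  # all-zero voxels are masked, not an error
  expect_true(all(!fw$ff$mask[tr$labels == 0]))
})

test_that("fitted FF matches a dense grid-search oracle on single voxels", {
  cfg <- tiny_config(sigma = 0.02, seed = 8)
  tr <- phantom_ground_truth(cfg)
  ser <- generate_dixon_series(cfg, tr)
  fw <- separate_fat_water(ser, mask = tr$labels > 0)
  te <- cfg$dixon_te_ms / 1000
  fat_hz <- ser$extra$fat_hz
  grid_oracle <- function(s) {
    best <- Inf; best_ff <- NA
    for (psi in seq(-80, 80, by = 1)) {
      for (t2s in c(15, 20, 25, 30, 40)) {
        u <- exp(2i * pi * psi * te) * exp(-te * 1000 / t2s)
        v <- exp(2i * pi * fat_hz * te) * u
        X <- cbind(c(Re(u), Im(u)), c(Re(v), Im(v)))
        yv <- c(Re(s), Im(s))
        ab <- pmax(qr.solve(X, yv), 0)
        r <- sum((yv - X %*% ab)^2)
        if (r < best) { best <- r; best_ff <- ab[2] / sum(ab) * 100 }
      }
    }
    best_ff
  }
  vox <- which(tr$labels %in% c(2, 3))[c(3, 77)]
  for (v in vox) {
    s <- sapply(1:3, function(k) ser$data[, , , k][v])
    expect_lt(abs(fw$ff$values[v] - grid_oracle(s)), 0.5)
  }
})

test_that("FF map is bounded and cCSA never exceeds CSA", {
  cfg <- tiny_config(sigma = 0.03, seed = 30)
  tr <- phantom_ground_truth(cfg)
  fw <- separate_fat_water(generate_dixon_series(cfg, tr),
                           mask = tr$labels > 0)
  v <- fw$ff$values[fw$ff$mask]
  expect_true(all(v >= 0 & v <= 100))
  csa <- compute_csa(tr$labels, cfg$spacing)
  rec <- aggregate_muscle(fw$ff, as_muscle_label_map(tr))
  cc <- compute_ccsa(csa$csa_mm2, rec$mean_value)
  expect_true(all(cc <= csa$csa_mm2 + 1e-12))
})
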