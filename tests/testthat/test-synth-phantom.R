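test_that("phantom generation is bit-identical for the same config and seed", {
  cfg <- tiny_config(sigma = 0.03, seed = 11)
  a <- generate_dixon_series(cfg)
  b <- generate_dixon_series(cfg)
  expect_identical(a$data, b$data)
  m1 <- generate_mse_series(cfg)
  m2 <- generate_mse_series(cfg)
  expect_identical(m1$data, m2$data)
  cfg2 <- tiny_config(sigma = 0.03, seed = 12)
  expect_false(identical(generate_dixon_series(cfg2)$data, a$data))
})

test_that("config validation rejects invalid layouts", {
  mus <- default_muscle_layout()
  mus$ff[1] <- 130
  expect_error(phantom_config(muscles = mus), "ff")
  mus <- default_muscle_layout(); mus$label[2] <- mus$label[1]
  expect_error(phantom_config(muscles = mus), "unique")
  mus <- default_muscle_layout(); mus$lambda3[1] <- mus$lambda1[1] + 1
  expect_error(phantom_config(muscles = mus), "descending")
  expect_error(phantom_config(sigma = -1), "sigma")
  expect_error(phantom_config(dixon_te_ms = c(3, 2, 5)), "increasing")
})

test_that("Dixon forward model matches the closed-form oracle", {
  cfg <- tiny_config(sigma = 0)
  tr <- phantom_ground_truth(cfg)
  ser <- generate_dixon_series(cfg, tr)
  fat_hz <- -3.4 * 127.73
  te <- c(2.75, 3.95, 5.15)
  vox <- which(tr$labels > 0)[c(1, 50, 400)]
  for (v in vox) {
    w <- 1 - tr$ff[v] / 100; f <- tr$ff[v] / 100
    oracle <- (w + f * exp(2i * pi * fat_hz * te / 1000)) *
      exp(2i * pi * tr$psi[v] * te / 1000) * exp(-te / tr$t2star[v])
    got <- sapply(1:3, function(k) ser$data[, , , k][v])
    expect_lt(max(Mod(got - oracle)) / max(Mod(oracle)), 1e-10)
  }
  # frozen spot check: FF = 30, psi = 30 Hz, T2* = 25 ms
  S <- (0.7 + 0.3 * exp(2i * pi * fat_hz * te / 1000)) *
    exp(2i * pi * 30 * te / 1000) * exp(-te / 25)
  expect_equal(S, c(0.749856531470334 + 0.137086915187585i,
                    0.229423462081178 + 0.551543451169631i,
                    0.534103838421018 + 0.349796427570777i),
               tolerance = 1e-12)
})

test_that("pure-water and pure-fat Dixon voxels behave as the model dictates", {
  mus <- default_muscle_layout()
  mus$ff <- rep(c(0, 100), 4)
  cfg <- tiny_config(sigma = 0, psi_amp_hz = 0, muscles = mus)
  tr <- phantom_ground_truth(cfg)
  ser <- generate_dixon_series(cfg, tr)
  v_w <- which(tr$labels == 1)[1]   # FF = 0
  mags <- sapply(1:3, function(k) Mod(ser$data[, , , k][v_w]))
  te <- cfg$dixon_te_ms
  # water only: |S| follows the pure T2* decay
  expect_equal(mags, exp(-te / tr$t2star[v_w]), tolerance = 1e-12)
  v_f <- which(tr$labels == 2)[1]   # FF = 100
  ph <- sapply(1:3, function(k) Arg(ser$data[, , , k][v_f]))
  dph <- diff(ph)
  fat_hz <- -3.4 * 127.73
  expected <- 2 * pi * fat_hz * diff(te) / 1000
  # compare on the unit circle (phase is only defined modulo 2 pi)
  expect_equal(exp(1i * dph), exp(1i * expected), tolerance = 1e-9)
})

test_that("multi-echo spin-echo decay matches the tri-exponential oracle", {
  mus <- default_muscle_layout()
  mus$ff[c(1, 5)] <- 0                  # one truly fat-free muscle pair
  cfg <- tiny_config(sigma = 0, muscles = mus)
  tr <- phantom_ground_truth(cfg)
  ser <- generate_mse_series(cfg, tr)
  te <- (1:17) * 9.5
  v <- which(tr$labels == 3)[10]   # FF = 30
  aw <- tr$b1[v] * 0.7; af <- tr$b1[v] * 0.3
  oracle <- aw * exp(-te / tr$t2w[v]) +
    af * (0.7 * exp(-te / 180) + 0.3 * exp(-te / 50))
  got <- sapply(1:17, function(k) ser$data[, , , k][v])
  expect_equal(got, oracle, tolerance = 1e-12)
  # FF = 0 muscle: log-signal exactly linear with slope -1/T2w
  v0 <- which(tr$labels == 1)[1]
  got0 <- sapply(1:17, function(k) ser$data[, , , k][v0])
  slopes <- diff(log(got0)) / diff(te)
  expect_equal(slopes, rep(-1 / tr$t2w[v0], 16), tolerance = 1e-10)
})

test_that("diffusion forward model matches the quadratic-form oracle", {
  cfg <- tiny_config(sigma = 0, psi_amp_hz = 0, olefinic_scale = 0)
  tr <- phantom_ground_truth(cfg)
  ser <- generate_dti_series(cfg, 100, tr)
  meta <- ser$meta
  v <- which(tr$labels == 2)[5]
  D <- matrix(0, 3, 3)
  comp <- sapply(1:6, function(k) tr$tensor[, , , k][v])
  D[1, 1] <- comp[1]; D[2, 2] <- comp[2]; D[3, 3] <- comp[3]
  D[1, 2] <- D[2, 1] <- comp[4]; D[1, 3] <- D[3, 1] <- comp[5]
  D[2, 3] <- D[3, 2] <- comp[6]
  b0 <- Mod(ser$data[, , , which(meta$bval == 0)[1]][v])
  for (i in which(meta$bval > 0 & meta$shift_ms == meta$shift_ms[1])) {
    g <- c(meta$gx[i], meta$gy[i], meta$gz[i])
    oracle <- b0 * exp(-meta$bval[i] * as.numeric(t(g) %*% D %*% g) * 1e-3)
    expect_equal(Mod(ser$data[, , , i][v]), oracle, tolerance = 1e-10)
  }
  # with no olefinic fat and psi = 0, magnitude is identical across shifts
  sel <- which(meta$bval == 0)
  mags <- sapply(sel, function(i) Mod(ser$data[, , , i][v]))
  expect_equal(mags, rep(mags[1], length(mags)), tolerance = 1e-12)
})

test_that("fingerprint recursion matches a hand-computed 3-pulse oracle", {
  sched <- fingerprint_schedule(flip_deg = c(30, 60, 90),
                                tr_ms = c(12, 500, 12), ti_ms = 20)
  got <- as.numeric(mrf_signal(1000, 1, sched))
  expect_equal(got, c(-0.480198673306755, -0.701375888787145,
                      0.147861082911992), tolerance = 1e-12)
})

test_that("generated spectrum places the carnosine peak at the configured shift", {
  cfg <- tiny_config(sigma = 0)
  sp <- generate_spectrum(cfg, muscle = "GM", side = "R")
  ph_true <- cfg$muscles$ph[cfg$muscles$code == "GM" & cfg$muscles$side == "R"]
  delta_true <- carnosine_shift(ph_true)
  mag <- Mod(sp$signal)
  win <- sp$ppm >= 7.5 & sp$ppm <= 8.7
  peak_ppm <- sp$ppm[win][which.max(mag[win])]
  expect_lt(abs(peak_ppm - delta_true), sp$resolution_ppm)
})

test_that("generated background noise matches the configured sigma", {
  cfg <- phantom_config(sigma = 0.04, seed = 21)
  tr <- phantom_ground_truth(cfg)
  ser <- generate_dti_series(cfg, 100, tr)
  bg <- which(tr$labels == 0)
  v <- ser$data[, , , 1][bg]          # complex noise in background
  expect_gt(length(v), 1e4)
  expect_lt(abs(sd(Re(v)) / 0.04 - 1), 0.05)
  expect_lt(abs(sd(Im(v)) / 0.04 - 1), 0.05)
})

test_that("generators validate their inputs", {
  cfg <- tiny_config()
  expect_error(generate_dti_series(cfg, directions = dti_directions()[1:4, ]),
               "6 diffusion directions")
  expect_error(fingerprint_schedule(flip_deg = numeric(0)), "empty")
  expect_error(generate_spectrum(cfg, muscle = "XX"), "not found")
})
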