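mk_map <- function(vals, mask = !is.na(vals), parameter = "ff") {
  quantitative_map(vals, mask, parameter = parameter, unit = "%")
}

mk_labels <- function(lab) {
  muscle_label_map(lab, tibble::tibble(
    label = sort(unique(as.integer(lab[lab > 0]))),
    code = c("TA", "SOL")[seq_along(sort(unique(as.integer(lab[lab > 0]))))],
    side = "R", compartment = "leg"))
}

test_that("aggregate_muscle averages valid voxels and applies the 50-voxel rule", {
  lab <- array(0L, c(20, 20, 1))
  lab[1:10, 1:20, 1] <- 1L          # 200 voxels
  lab[11:17, 1:7, 1] <- 2L          # 49 voxels
  vals <- array(NA_real_, dim(lab))
  vals[lab == 1L] <- 7
  vals[lab == 2L] <- 3
  rec <- aggregate_muscle(mk_map(vals), mk_labels(lab))
  expect_equal(rec$mean_value[rec$muscle == "TA"], 7)
  expect_false(rec$excluded[rec$muscle == "TA"])
  expect_true(rec$excluded[rec$muscle == "SOL"])
  expect_equal(rec$reason[rec$muscle == "SOL"], "too_few_voxels")
  expect_equal(rec$n_voxels, c(200L, 49L))
  # exactly 50 voxels is retained (strict rule)
  lab2 <- array(0L, c(20, 20, 1)); lab2[1:10, 1:5, 1] <- 1L
  v2 <- array(NA_real_, dim(lab2)); v2[lab2 == 1L] <- 4
  lm2 <- muscle_label_map(lab2, tibble::tibble(label = 1L, code = "TA",
                                               side = "R",
                                               compartment = "leg"))
  expect_false(aggregate_muscle(mk_map(v2), lm2)$excluded)
  # a two-value muscle averages plainly
  vals[lab == 1L] <- rep(c(10, 20), each = 100)
  expect_equal(aggregate_muscle(mk_map(vals), mk_labels(lab))$mean_value[1],
               15)
  # absent label: count 0, excluded, no error
  lab3 <- lab; lab3[lab3 == 2L] <- 0L
  lm3 <- muscle_label_map(lab3, tibble::tibble(
    label = c(1L, 2L), code = c("TA", "SOL"), side = "R",
    compartment = "leg"))
  rec3 <- aggregate_muscle(mk_map(vals), lm3)
  expect_equal(rec3$n_voxels[rec3$muscle == "SOL"], 0L)
  expect_true(rec3$excluded[rec3$muscle == "SOL"])
})

test_that("weighted_average is pixel-weighted and respects scope", {
  rec <- tibble::tibble(
    subject = "s1", group = "patient", visit = "BL", side = "R",
    muscle = c("TA", "GM"), compartment = "leg", parameter = "ff",
    mean_value = c(10, 20), n_voxels = c(100L, 300L),
    excluded = FALSE, reason = "none")
  expect_equal(weighted_average(rec), 17.5)
  expect_equal(weighted_average(rec[1, ]), 10)
  expect_equal(weighted_average(rec, "global_leg"), 17.5)
  expect_warning(v <- weighted_average(rec, "global_thigh"), "unavailable")
  expect_true(is.na(v))
  # group scope: TRIC contains GM but not TA
  expect_equal(weighted_average(rec, "group", group = "TRIC"), 20)
  # result always within the range of contributing means
  set.seed(2)
  for (i in 1:10) {
    r <- rec[rep(1, 5), ]
    r$mean_value <- runif(5, 0, 60); r$n_voxels <- sample.int(500, 5)
    w <- weighted_average(r)
    expect_gte(w, min(r$mean_value)); expect_lte(w, max(r$mean_value))
  }
})

test_that("bilateral averaging is voxel-count weighted and flags unilateral", {
  rec <- tibble::tibble(
    subject = "s1", group = "patient", visit = "BL",
    side = c("L", "R", "L"),
    muscle = c("TA", "TA", "GM"), compartment = "leg", parameter = "ff",
    mean_value = c(10, 20, 33), n_voxels = c(100L, 100L, 80L),
    excluded = FALSE, reason = "none")
  out <- bilateral_average(rec)
  ta <- out[out$muscle == "TA", ]
  expect_equal(ta$mean_value, 15)
  expect_equal(ta$n_voxels, 200L)
  expect_false(ta$unilateral)
  gm <- out[out$muscle == "GM", ]
  expect_equal(gm$mean_value, 33)
  expect_true(gm$unilateral)
  # asymmetric counts equal pooled-voxel mean
  rec$n_voxels <- c(100L, 300L, 80L)
  out2 <- bilateral_average(rec)
  expect_equal(out2$mean_value[out2$muscle == "TA"],
               (10 * 100 + 20 * 300) / 400)
})

test_that("cohort tallies reproduce the study bookkeeping", {
  tal <- tally_cohort(c(BL = 18, y1 = 16, y2 = 16), controls = 13)
  get <- function(mod, grp) tal$n_muscles[tal$modality == mod &
                                            tal$group == grp]
  expect_equal(get("bilateral_qmri", "total"), 2268)
  expect_equal(get("bilateral_qmri", "patient"), 1800)
  expect_equal(get("bilateral_qmri", "control"), 468)
  expect_equal(get("dti", "total"), 441)
  # single subject, single visit, one muscle, bilateral
  tal1 <- tally_cohort(1, controls = 0, thigh_muscles = 0, leg_muscles = 1)
  expect_equal(tal1$n_muscles[tal1$modality == "bilateral_qmri" &
                                tal1$group == "total"], 2)
})

test_that("delta and SRM follow their definitions", {
  df <- tibble::tibble(subject = rep(c("a", "b", "c"), each = 2),
                       visit = rep(c("BL", "y2"), 3),
                       mean_value = c(10, 12, 5, 6, 8, 11))
  d <- delta_over_time(df)
  expect_equal(d$delta$delta, c(2, 1, 3))
  expect_equal(d$mean, 2)
  expect_equal(standardized_response_mean(d), 2 / 1)
  expect_equal(standardized_response_mean(c(1, 2, 3)), 2)
  expect_equal(standardized_response_mean(c(-2, -1, 1, 2)), 0)
  expect_warning(s0 <- standardized_response_mean(c(1, 1, 1)), "zero SD")
  expect_true(is.na(s0))
  # identical visits: mean 0, sd 0
  df2 <- df; df2$mean_value <- rep(c(4, 4), 3)
  d2 <- delta_over_time(df2)
  expect_equal(d2$mean, 0); expect_equal(d2$sd, 0)
  # unpaired subjects dropped with warning
  df3 <- df[-6, ]
  expect_warning(d3 <- delta_over_time(df3), "unpaired")
  expect_equal(d3$n, 2)
  # mean delta equals difference of visit means on complete pairs
  expect_equal(d$mean, mean(df$mean_value[df$visit == "y2"]) -
                 mean(df$mean_value[df$visit == "BL"]))
})

test_that("SRM is invariant to affine unit changes and matches its sign", {
  set.seed(4)
  d <- rnorm(60, 1, 2)
  expect_equal(standardized_response_mean(d * 9.5),
               standardized_response_mean(d), tolerance = 1e-12)
  expect_equal(sign(standardized_response_mean(d)), sign(mean(d)))
})

test_that("Spearman with ties agrees with the brute-force mid-rank oracle", {
  set.seed(7)
  for (n in 3:8) {
    for (rep in 1:15) {
      x <- sample(1:4, n, replace = TRUE)
      y <- sample(1:4, n, replace = TRUE)
      if (sd(x) == 0 || sd(y) == 0) next
      got <- spearman_correlation(x, y)$rho
      expect_equal(got, spearman_oracle(x, y), tolerance = 1e-12)
    }
  }
  expect_equal(spearman_correlation(1:5, exp(1:5))$rho, 1)
  expect_equal(spearman_correlation(1:5, -(1:5)^3)$rho, -1)
  expect_equal(spearman_correlation(1:5, exp(1:5))$band, "very strong")
  expect_warning(r <- spearman_correlation(rep(1, 4), 1:4), "constant")
  expect_true(is.na(r$rho))
})

test_that("correlation bands follow the printed cut points", {
  expect_equal(correlation_band(c(0.1, 0.25, -0.45, 0.7, 0.95)),
               c("very weak", "weak", "moderate", "strong", "very strong"))
  expect_equal(correlation_band(0.19), "very weak")
  expect_equal(correlation_band(0.20), "weak")
})

test_that("rank tests agree with exhaustive small-n oracles", {
  set.seed(11)
  for (rep in 1:10) {
    n <- sample(4:8, 1)
    x <- rnorm(n); y <- rnorm(n)      # continuous: no ties, no zeros
    got <- wilcoxon_signed_rank(x, y)$p_value
    expect_equal(got, signed_rank_p_oracle(x, y), tolerance = 1e-12)
  }
  for (rep in 1:10) {
    n <- sample(3:6, 1); m <- sample(3:6, 1)
    x <- rnorm(n); y <- rnorm(m)
    got <- mann_whitney_u(x, y)$p_value
    expect_equal(got, mann_whitney_p_oracle(x, y), tolerance = 1e-12)
  }
})

test_that("Bonferroni levels match the printed values", {
  expect_equal(significance_levels(9), 0.0056)
  expect_equal(significance_levels(20), 0.0025)
  expect_equal(significance_levels(1), 0.05)
  expect_error(significance_levels(0), ">= 1")
})

test_that("the long table round-trips and its ledger conserves counts", {
  lab <- array(0L, c(20, 20, 1)); lab[1:10, , 1] <- 1L; lab[12:19, 1:6, 1] <- 2L
  vals <- array(NA_real_, dim(lab)); vals[lab > 0] <- 5
  rec <- aggregate_muscle(mk_map(vals), mk_labels(lab))
  path <- file.path(tempdir(), "records.csv")
  export_long_table(rec, path)
  back <- read_long_table(path)
  expect_equal(nrow(back), nrow(rec))
  expect_equal(back$mean_value, rec$mean_value)
  expect_equal(back$reason, rec$reason)
  led <- records_ledger(rec)
  expect_equal(sum(led$n), nrow(rec))
  expect_true(all(led$retained + sum(led$n[led$reason != "none"]) ==
                    led$total))
  # empty study: header-only CSV
  path2 <- file.path(tempdir(), "empty.csv")
  export_long_table(rec[0, ], path2)
  expect_equal(nrow(read_long_table(path2)), 0)
})
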