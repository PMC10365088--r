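test_that("AVD and Dice reproduce their closed-form cases", {
  a <- array(FALSE, rep(20, 3)); a[1:2000] <- TRUE
  b <- array(FALSE, rep(20, 3)); b[1:1000] <- TRUE
  expect_equal(avd(a, a, 1), 0)
  expect_equal(avd(a, b, 1), 1.0)
  expect_equal(avd(b, a, 1), 1.0)                 # symmetric
  expect_equal(avd(a, b, 1.14), 1.14^3, tolerance = 1e-12)  # 1.481544 ml

  expect_equal(dice3d(a, a), 1.0)
  d1 <- array(FALSE, rep(20, 3)); d1[1:100] <- TRUE
  d2 <- array(FALSE, rep(20, 3)); d2[101:200] <- TRUE
  expect_equal(dice3d(d1, d2), 0.0)
  o1 <- array(FALSE, rep(20, 3)); o1[1:100] <- TRUE
  o2 <- array(FALSE, rep(20, 3)); o2[51:150] <- TRUE
  expect_equal(dice3d(o1, o2), 0.5)
  expect_equal(dice3d(o2, o1), 0.5)
  empty <- array(FALSE, rep(20, 3))
  expect_equal(dice3d(empty, empty), 1.0)
  expect_error(avd(a, array(FALSE, rep(10, 3)), 1), class = "shape_error")

  # both metrics invariant to an identical rigid shift of both masks
  sh <- function(m) { out <- array(FALSE, dim(m)); out[, , 2:20] <- m[, , 1:19]; out }
  expect_equal(dice3d(sh(o1), sh(o2)), dice3d(o1, o2))
  expect_equal(avd(sh(o1), sh(o2), 2), avd(o1, o2, 2))
})

test_that("best-bin selection follows the stated objective and tie rule", {
  expect_equal(select_best(c(5, 3, 7, 9), "min"), 2)
  expect_equal(select_best(c(0.8, 0.9, 0.9, 0.7), "max"), 2)
  expect_equal(select_best(4.2, "min"), 1)
  expect_equal(select_best(c(NA, 2, NA, 3), "min"), 2)
  expect_error(select_best(c(NA_real_, NA_real_), "max"), class = "metric_error")
})

test_that("the paired t-test matches the textbook formula and t.test", {
  x <- c(3, 5, 9, 11); y <- c(2, 3, 6, 7)   # d = 1,2,3,4
  r <- paired_t(x, y)
  expect_equal(r$t, 2.5 / (sd(1:4) / 2), tolerance = 1e-12)
  expect_equal(r$t, 3.873, tolerance = 1e-3)
  expect_equal(r$p, 0.0305, tolerance = 1e-2)
  ref <- t.test(x, y, paired = TRUE)
  expect_equal(r$t, unname(ref$statistic), tolerance = 1e-12)
  expect_equal(r$p, ref$p.value, tolerance = 1e-12)
  expect_equal(r$n, 4)

  expect_error(paired_t(c(1, 2, 3), c(0, 1, 2)), class = "degenerate_variance")
  expect_error(paired_t(1:3, 1:2), class = "metric_error")
})

test_that("sharpness equals the ideal-step closed form and is blur-monotone", {
  n <- 64
  g <- image_grid(n, 220)
  an <- sphere_anatomy(r = 30, motion = 0)
  ras <- rasterize(an, 0, g)
  # one-voxel step sampled with linear interpolation: 20-80% width = 0.6 dx
  # (exact along grid axes, so probe with the four axis-aligned rays)
  s4 <- sharpness(ras$volume, ras$mask, g$spacing, n_rays = 4)
  expect_equal(as.numeric(s4), 1 / (0.6 * g$spacing), tolerance = 0.02)
  s <- sharpness(ras$volume, ras$mask, g$spacing)

  vals <- vapply(c(0.5, 1, 2, 4) * g$spacing, function(sig)
    as.numeric(sharpness(gaussian_blur3d(ras$volume, sig, g$spacing),
                         ras$mask, g$spacing)), numeric(1))
  expect_true(all(diff(vals) < 0))

  # radial measure: a quarter-turn about SI leaves it unchanged
  rot <- aperm(ras$volume, c(2, 1, 3))[n:1, , ]
  rotm <- aperm(ras$mask, c(2, 1, 3))[n:1, , ]
  s2 <- sharpness(rot, rotm, g$spacing)
  expect_lt(abs(s2 - s) / s, 0.05)

  expect_error(sharpness(ras$volume, array(FALSE, dim(ras$mask)), g$spacing),
               class = "sharpness_undefined")
})

test_that("study evaluation assembles metrics, best bins, and paired tests", {
  g <- image_grid(32, 220)
  an <- heart_anatomy()
  base <- rasterize(an, 0, g)
  vol <- base$volume
  truth <- base$mask
  grow <- function(m, k) { # dilate k times along +z to inflate the volume
    out <- m
    for (i in seq_len(k)) {
      s <- array(FALSE, dim(out)); s[, , 2:dim(out)[3]] <- out[, , 1:(dim(out)[3] - 1)]
      out <- out | s
    }
    out
  }
  subj <- function(best_bin) {
    mres <- lapply(1:4, function(b) {
      off <- if (b == best_bin) 0 else b  # bin `best_bin` matches manual best
      list(volume = vol, auto = grow(truth, off))
    })
    list(mcorr = list(volume = vol, auto = grow(truth, 2)),
         mres = mres,
         manual = list(mcorr = truth, mres = replicate(4, truth, simplify = FALSE)))
  }
  rep2 <- evaluate_study(list(subj(2), subj(2), subj(2)), spacing = g$spacing)
  expect_s3_class(rep2, "metrics_report")
  expect_equal(nrow(rep2$per_recon), 3 * 5)
  expect_true(all(rep2$best_bins$best_avd_bin == 2))
  expect_true(all(rep2$best_bins$best_dice_bin == 2))
  expect_true(all(c("avd_ml", "dice", "sharpness_per_mm") %in%
                  names(rep2$per_recon)))
  bt <- rep2$tests[rep2$tests$comparison == "mcorr_vs_best_mres" &
                   rep2$tests$metric == "avd_ml", ]
  expect_gt(bt$mean_diff, 0)  # mcorr AVD worse than best-mres AVD

  # identical masks everywhere: zero AVD, Dice 1, degenerate tests reported NA
  ident <- list(mcorr = list(volume = vol, auto = truth),
                mres = replicate(4, list(volume = vol, auto = truth),
                                 simplify = FALSE),
                manual = list(mcorr = truth,
                              mres = replicate(4, truth, simplify = FALSE)))
  rep0 <- evaluate_study(list(ident, ident), spacing = g$spacing)
  expect_true(all(rep0$per_recon$avd_ml == 0))
  expect_true(all(rep0$per_recon$dice == 1))
  expect_true(all(is.na(rep0$tests$p)))

  # report files round-trip
  dir <- file.path(tempdir(), "report_test")
  write_metrics_report(rep2, dir)
  expect_true(file.exists(file.path(dir, "metrics_per_recon.csv")))
  expect_true(file.exists(file.path(dir, "paired_tests.csv")))
  expect_true(file.exists(file.path(dir, "metrics_boxplots.pdf")))
})
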