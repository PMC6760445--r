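toy_series <- function(A, B, x, id = "c") {
  structure(list(crystal_id = id, x = x, y = A * exp(-B * x),
                 n = rep(1L, length(x)),
                 filters_applied = list()), class = "intensity_series")
}

test_that("frame mean intensity applies tilt and resolution filters", {
  geom <- toy_geom()
  led <- exposure_ledger(geom, 3)
  tab <- data.frame(h = 1, k = 1, l = 1,
                    frame = c(1, 1, 2, 2, 3),
                    intensity = c(10, 20, 30, 99, 50),
                    sigma = 1,
                    tilt_deg = c(0, 10, -20, 45, 0),   # 45 excluded
                    d = c(5, 8, 10, 5, 30))            # 30 A outside (2.7, 20)
  s <- frame_mean_intensity(tab, led, tilt_range = c(-30, 30),
                            resolution_range = c(2.70, 20.0))
  expect_equal(s$y, c(15, 30))                # frame 3 fully filtered out
  expect_equal(s$x, led$cumulative_exposure[1:2])
  expect_equal(s$n, c(2L, 1L))
  # boundary is closed: tilt exactly 30 is kept
  tab2 <- tab; tab2$tilt_deg[4] <- 30
  expect_equal(frame_mean_intensity(tab2, led)$y[2], mean(c(30, 99)))
  expect_error(frame_mean_intensity(tab, led, tilt_range = c(80, 90)),
               "removed")
})

test_that("shared decay fit recovers noiseless parameters to optimizer tolerance", {
  x <- seq(0.1, 3, by = 0.1)
  series <- list(toy_series(100, 0.277, x, "a"),
                 toy_series(50, 0.277, x, "b"),
                 toy_series(80, 0.277, x, "c"))
  m <- fit_shared_decay(series)
  expect_equal(m$B, 0.277, tolerance = 1e-6)
  expect_equal(unname(m$A), c(100, 50, 80), tolerance = 1e-6)
  expect_equal(m$D50, log(2) / 0.277, tolerance = 1e-6)
  expect_equal(m$D50, 2.50, tolerance = 1e-2)

  # sharing is well-posed: duplicating a series leaves B unchanged
  m1 <- fit_shared_decay(list(toy_series(100, 0.5, x)))
  m2 <- fit_shared_decay(list(toy_series(100, 0.5, x, "p"),
                              toy_series(100, 0.5, x, "q")))
  expect_equal(m1$B, m2$B, tolerance = 1e-8)

  # constant series: B ~ 0 (numerical optimum may land on either side of 0)
  flat <- toy_series(42, 0, x)
  m0 <- suppressWarnings(fit_shared_decay(list(flat)))
  expect_lt(abs(m0$B), 1e-6)
  # increasing intensities: fitted B < 0 flags "no damage detectable"
  expect_warning(mneg <- fit_shared_decay(list(toy_series(10, -0.3, x))),
                 "no damage")
  expect_lt(mneg$B, 0)
  expect_true(is.na(mneg$D50))

  expect_error(fit_shared_decay(list(toy_series(10, 1, c(0, 1)))), ">= 3")
})

test_that("noisy decay recovery is within 10% over Monte-Carlo replicates", {
  x <- seq(0.05, 2.5, by = 0.05)
  B_true <- 0.277
  set.seed(41)
  est <- replicate(100, {
    series <- lapply(c(100, 50, 80), function(A) {
      s <- toy_series(A, B_true, x)
      s$y <- s$y * (1 + 0.05 * rnorm(length(x)))
      s
    })
    fit_shared_decay(series)$B
  })
  expect_lt(abs(mean(est) - B_true) / B_true, 0.03)   # unbiased within MC error
  expect_true(all(abs(est - B_true) / B_true < 0.10))
})

test_that("D50 is the reciprocal identity ln2/B", {
  expect_equal(d50(log(2) / 2.5), 2.5)
  expect_equal(d50(log(2) / 1.6), 1.6)
  expect_equal(d50(2 * 0.4), d50(0.4) / 2)
  expect_error(d50(0), "undefined")
  expect_error(d50(-1), "undefined")
})

test_that("completeness versus exposure is monotone and matches ground truth", {
  geom <- toy_geom()
  cfg <- simulation_config(geom, cell = unit_cell(20, 20, 30),
                           n_frames = 100, decay_B = 0.277, d_min = 2.5,
                           obs_per_frame = NULL, seed = 42)
  sim <- simulate_reflection_table(cfg, n_crystals = 1, noise_cv = 0)
  tab <- sim$tables[[1]]
  led <- exposure_ledger(geom, 100)
  cutoffs <- seq(0.05, 1.05, by = 0.05)
  curve <- completeness_vs_exposure(tab, led, cfg$cell, "4/mmm",
                                    d_min = cfg$d_min, cutoffs = cutoffs)
  expect_true(all(diff(curve$completeness) >= -1e-12))
  expect_true(all(diff(curve$multiplicity) >= -1e-12))
  # cutoff below every frame exposure: zeros
  expect_equal(curve$completeness[cutoffs < led$cumulative_exposure[1]],
               numeric(0))
  z <- completeness_vs_exposure(tab, led, cfg$cell, "4/mmm", cfg$d_min,
                                cutoffs = 0.005)
  expect_equal(z$completeness, 0)
  expect_equal(z$multiplicity, 0)
  # cutoff above everything equals the full merge
  full <- merge_stats(tab, cfg$cell, "4/mmm", cfg$d_min)
  top <- completeness_vs_exposure(tab, led, cfg$cell, "4/mmm", cfg$d_min,
                                  cutoffs = 10)
  expect_equal(top$completeness, full$completeness)
  expect_equal(top$multiplicity, full$multiplicity)

  # ground-truth first passage: the simulator cycles the unique set twice
  # over the movie, so full completeness arrives near half the scan; the
  # 95% crossing from the curve must match a direct per-frame scan
  uniq_n <- nrow(sim$truth$unique_set)
  seen <- rep(FALSE, uniq_n)
  key_all <- paste(sim$truth$unique_set[, 1], sim$truth$unique_set[, 2],
                   sim$truth$unique_set[, 3])
  first_pass <- NA
  for (f in 1:100) {
    sub <- tab[tab$frame == f, ]
    asu <- map_to_asu(sub$h, sub$k, sub$l, "4/mmm")
    seen[match(paste(asu[, 1], asu[, 2], asu[, 3]), key_all)] <- TRUE
    if (mean(seen) >= 0.95) { first_pass <- led$cumulative_exposure[f]; break }
  }
  e95 <- exposure_at_completeness(curve, 0.95)
  expect_lt(abs(e95 - first_pass), 0.06)     # within one cutoff step

  # multiplicity grows linearly with exposure once the unique set is
  # covered (before that, new observations also add new unique reflections)
  grow <- curve$completeness >= max(curve$completeness) - 1e-9
  fitlm <- lm(curve$multiplicity[grow] ~ curve$exposure_cutoffs[grow])
  expect_gt(coef(fitlm)[2], 0)
  expect_gt(summary(fitlm)$r.squared, 0.99)
})

test_that("exposure_at_completeness interpolates between knots", {
  curve <- structure(list(exposure_cutoffs = c(0.2, 0.4, 0.6),
                          completeness = c(0.5, 0.8, 0.95),
                          multiplicity = c(1, 2, 3)),
                     class = "completeness_curve")
  expect_equal(exposure_at_completeness(curve, 0.95), 0.6)    # exact knot
  expect_equal(exposure_at_completeness(curve, 0.8), 0.4)
  # halfway between 0.8 and 0.95 -> halfway between 0.4 and 0.6
  expect_equal(exposure_at_completeness(curve, 0.875), 0.5)
  expect_error(exposure_at_completeness(curve, 0.99), "never reached")
  expect_error(exposure_at_completeness(curve, 1.01), "\\(0, 1\\]")
})

test_that("rocking-curve fit recovers Gaussian parameters", {
  phi <- seq(-1.35, 3.15, by = 0.45)
  I <- 100 * exp(-(phi - 0.9)^2 / (2 * 0.5^2))
  fit <- fit_rocking_curve(phi, I)
  expect_equal(fit$center, 0.9, tolerance = 1e-4)
  expect_equal(fit$width, 0.5, tolerance = 1e-4)
  expect_equal(fit$height, 100, tolerance = 1e-4)

  # translation equivariance
  fit2 <- fit_rocking_curve(phi + 2.5, I)
  expect_equal(fit2$center, 0.9 + 2.5, tolerance = 1e-6)
  expect_equal(fit2$width, fit$width, tolerance = 1e-6)

  # symmetric data: center at the axis of symmetry
  phis <- seq(-2, 2, by = 0.5)
  fit3 <- fit_rocking_curve(phis, 50 * exp(-phis^2 / 2), rep(2, length(phis)))
  expect_equal(fit3$center, 0, tolerance = 1e-6)

  # all intensity on one frame: width floored at half the frame spacing
  spike <- c(0, 0, 100, 0, 0)
  expect_warning(fd <- fit_rocking_curve(seq(0, 1.8, by = 0.45), spike),
                 "floor")
  expect_equal(fd$width, 0.45 / 2)
  expect_error(fit_rocking_curve(1:3, 1:3), ">= 4")
})
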