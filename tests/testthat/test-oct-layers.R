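# Layer segmentation: peak finding, RPE identification, boundary recovery,
# flattening, montage, exclusion, and cohort statistics.

test_that("find_peaks matches the brute-force prominence oracle", {
  set.seed(42)
  for (rep in 1:20) {
    x <- as.numeric(gauss_smooth_r(stats::rnorm(80), 1.2))
    got <- find_peaks(x, min_prominence = 0.2)
    want <- oracle_peaks(x, min_prominence = 0.2)
    expect_equal(got$index, want$index)
    expect_equal(got$prominence, want$prominence, tolerance = 1e-12)
  }
})

test_that("find_rpe picks the second hyperreflective band from the sclerad side", {
  scale <- 1.6
  z <- (0:299) * scale
  mk <- function(depths, amps) {
    x <- rep(0.05, 300)
    for (k in seq_along(depths))
      x <- x + amps[k] * exp(-(z - depths[k])^2 / (2 * 5^2))
    x
  }
  # peaks at 160, 320, 400, 440 um: second from the deep end is 400
  x <- mk(c(160, 320, 400, 440), c(0.5, 0.6, 0.8, 0.5))
  expect_equal(find_rpe(x, axial_scale = scale, smooth_sigma = 0), 400,
               tolerance = scale)
  # single-peak profile: failed (NA), not an error
  expect_true(is.na(find_rpe(mk(200, 0.8), axial_scale = scale)))
  # brute-force oracle: all prominent maxima sorted by depth descending,
  # index 2
  set.seed(7)
  for (rep in 1:10) {
    depths <- sort(sample(seq(80, 440, by = 40), 4))
    x <- mk(depths, stats::runif(4, 0.4, 0.9))
    pk <- oracle_peaks(x, min_prominence = 0.1 * diff(range(x)))
    want <- (sort(pk$index, decreasing = TRUE)[2] - 1) * scale
    expect_equal(find_rpe(x, axial_scale = scale, smooth_sigma = 0), want,
                 tolerance = 2 * scale)
  }
})

test_that("extract_lrps averages repeat frames", {
  dat <- array(0, dim = c(4, 3, 8))
  base <- matrix(seq_len(24), 3, 8)
  for (f in 1:4) dat[f, , ] <- base
  vol <- new_oct_volume(dat, 1.6, 0.01, 1.5, scan_mode = "linescan",
                        n_repeats = 4L)
  lrps <- extract_lrps(vol)
  expect_length(lrps, 3L)
  expect_equal(lrps[[1]]$reflectivity, base[1, ])   # idempotent mean
  dat2 <- dat
  dat2[1, 1, 1] <- 1; dat2[2, 1, 1] <- 3; dat2[3, 1, 1] <- 1; dat2[4, 1, 1] <- 3
  vol2 <- new_oct_volume(dat2, 1.6, 0.01, 1.5, scan_mode = "linescan",
                         n_repeats = 4L)
  expect_equal(extract_lrps(vol2)[[1]]$reflectivity[1], 2)  # mean of {1,3}
  expect_error(extract_lrps(vol, repeats = 3), "divide")
})

test_that("segmentation boundaries are ordered and recover ground truth", {
  sim <- gen_oct_volume(small_linescan(seed = 7, noise_sd = 0,
                                       rosettes = c(all = 0)))
  gt <- sim$ground_truth
  seg <- segment_volume(sim$volume)
  ok <- seg$quality_flag == "ok"
  expect_true(all(ok))
  # ordering invariant for every ok A-scan
  expect_true(all(seg$vitreoretinal_interface[ok] < seg$opl_sclerad_trough[ok]))
  expect_true(all(seg$opl_sclerad_trough[ok] < seg$pre_rpe_trough[ok]))
  expect_true(all(seg$pre_rpe_trough[ok] < seg$rpe_peak[ok]))
  # noise-free recovery within one axial pixel, 100% of ok A-scans
  expect_true(all(abs(seg$onl_plus_um - gt$onl_plus_map) <= 1.6))
  expect_true(all(abs(seg$total_um - gt$total_thickness_map) <= 1.6))
  # boundary ordering also holds under noise
  simn <- gen_oct_volume(small_linescan(seed = 8, noise_sd = 0.02,
                                        n_repeats = 2))
  segn <- segment_volume(simn$volume)
  okn <- segn$quality_flag == "ok"
  expect_gt(mean(okn), 0.9)
  expect_true(all(segn$opl_sclerad_trough[okn] < segn$pre_rpe_trough[okn]))
})

test_that("rosette A-scans are flagged for exclusion (lrp mode)", {
  sim <- gen_oct_volume(small_linescan(seed = 11, n_lrps = 240,
                                       noise_sd = 0.02, n_repeats = 2,
                                       rosettes = NULL))
  gt <- sim$ground_truth
  seg <- segment_volume(sim$volume)
  hit <- gt$rosette_mask
  expect_gt(sum(hit), 0)
  # every A-scan whose ONL is disrupted by a planted rosette is not 'ok'
  expect_true(all(seg$quality_flag[hit] != "ok"))
  # the vast majority of clean A-scans are kept
  expect_gt(mean(seg$quality_flag[!hit] == "ok"), 0.95)
})

test_that("flatten straightens a curved RPE and is the identity when flat", {
  p <- small_linescan(seed = 3, noise_sd = 0, onl_sd = 0, total_sd = 0,
                      rosettes = c(all = 0),
                      rpe_curvature_amplitude = 20)
  sim <- gen_oct_volume(p)
  flat <- flatten(sim$volume)
  seg <- segment_volume(flat)
  expect_lte(stats::sd(seg$rpe_peak), 1.6)   # RPE depth SD <= 1 px
  # shift map equals the negated curvature field within ~1 px
  sh_um <- as.vector(attr(flat, "shift_px")) * 1.6
  curv <- sim$ground_truth$rpe_depth_map - mean(sim$ground_truth$rpe_depth_map)
  expect_lt(max(abs(sh_um + curv - mean(sh_um + curv))), 2 * 1.6)
  # already-flat volume: all shifts zero
  p0 <- small_linescan(seed = 3, noise_sd = 0, onl_sd = 0, total_sd = 0,
                       rosettes = c(all = 0), rpe_curvature_amplitude = 0)
  flat0 <- flatten(gen_oct_volume(p0)$volume)
  expect_true(all(attr(flat0, "shift_px") == 0))
  expect_equal(flat0$data, gen_oct_volume(p0)$volume$data)
})

test_that("flatten-then-segment commutes with segment on noise-free phantoms", {
  sim <- gen_oct_volume(small_linescan(seed = 5, noise_sd = 0,
                                       rosettes = c(all = 0),
                                       rpe_curvature_amplitude = 15))
  seg_direct <- segment_volume(sim$volume)
  seg_flat <- segment_volume(flatten(sim$volume))
  ok <- seg_direct$quality_flag == "ok" & seg_flat$quality_flag == "ok"
  expect_gt(mean(ok), 0.99)
  expect_true(all(abs(seg_direct$onl_plus_um[ok] - seg_flat$onl_plus_um[ok]) <= 1.6))
  expect_true(all(abs(seg_direct$total_um[ok] - seg_flat$total_um[ok]) <= 1.6))
})

test_that("montage_profiles unions overlapping segments and averages overlaps", {
  grid <- seq(-0.75, 0.75, by = 0.05)
  mk <- function(v) thickness_profile(grid, rep(v, length(grid)))
  m <- montage_profiles(list(mk(60), mk(60), mk(60)), c(-0.8, 0, 0.8))
  expect_equal(diff(range(m$position_mm)), 3.1, tolerance = 0.05)
  expect_true(all(m$value_um[m$mask] == 60))     # mean of equals
  # overlap of 60 and 64 averages to 62
  m2 <- montage_profiles(list(mk(60), mk(64)), c(-0.5, 0.5))
  mid <- m2$position_mm > -0.25 & m2$position_mm < 0.25
  expect_true(all(m2$value_um[mid] == 62))
  left <- m2$position_mm < -0.3
  expect_true(all(m2$value_um[left] == 60))
  expect_error(montage_profiles(list(mk(60), mk(64)), c(-2, 2)),
               "overlap")
})

test_that("exclude_regions applies the ONH zone and rosette masks", {
  grid <- seq(-1.2, 1.2, by = 0.01)
  prof <- thickness_profile(grid, rep(66, length(grid)))
  ex <- exclude_regions(prof)
  expect_true(all(!ex$mask[abs(grid) < 0.09]))
  expect_true(all(ex$mask[abs(grid) >= 0.09]))
  # rosette flags covering the superior half invalidate it
  ex2 <- exclude_regions(prof, rosette_mask = grid > 0)
  expect_true(all(!ex2$mask[grid > 0]))
  expect_true(all(ex2$mask[grid <= -0.09]))
  expect_error(exclude_regions(prof, rosette_mask = rep(TRUE, length(grid))),
               "all positions excluded")
  # masking spiky rosette artifacts restores the clean mean
  clean <- rep(66, length(grid))
  spiky <- clean
  art <- sample(seq_along(grid), 40)
  spiky[art] <- clean[art] - 35
  pr <- thickness_profile(grid, spiky)
  masked <- exclude_regions(pr, rosette_mask = seq_along(grid) %in% art)
  expect_equal(mean(masked$value_um[masked$mask]), 66)
  expect_lt(mean(pr$value_um), 66 - 1)
})

test_that("profile_mean_sd pools points or summarises per eye", {
  grid <- seq(-1, 1, by = 0.1)
  mk <- function(v) thickness_profile(grid, rep(v, length(grid)))
  s <- profile_mean_sd(list(mk(66.4)))
  expect_equal(s$mean, 66.4)
  expect_equal(s$sd, 0)
  s2 <- profile_mean_sd(list(mk(60), mk(70)), per_eye = TRUE)
  expect_equal(s2$mean, 65)
  expect_equal(s2$n, 2L)
  # brute-force check on random masked inputs
  set.seed(3)
  profs <- lapply(1:5, function(i) {
    v <- stats::rnorm(length(grid), 60, 5)
    thickness_profile(grid, v, mask = stats::runif(length(grid)) > 0.3)
  })
  got <- profile_mean_sd(profs)
  allv <- unlist(lapply(profs, function(p) p$value_um[p$mask]))
  expect_equal(got$mean, mean(allv))
  expect_equal(got$sd, stats::sd(allv))
})

test_that("fraction_vs_baseline normalises to the youngest cohort", {
  cs <- function(m) structure(list(mean = m, sd = 1, n = 5, group_label = ""),
                              class = "cohort_summary")
  expect_equal(fraction_vs_baseline(cs(54.7), cs(66.4)), 0.824,
               tolerance = 5e-4)
  expect_equal(fraction_vs_baseline(cs(66.4), cs(66.4)), 1.0)
  expect_equal(fraction_vs_baseline(cs(0), cs(66.4)), 0.0)
  expect_error(fraction_vs_baseline(cs(50), cs(0)), "> 0")
})

test_that("compare_groups is an unpaired two-tailed t-test", {
  expect_equal(compare_groups(c(1, 2, 3), c(1, 2, 3)),
               list(t = 0, p = 1, df = 4), tolerance = 1e-12)
  sep <- compare_groups(c(1, 2, 3), c(11, 12, 13) + stats::rnorm(3, 0, 1e-3))
  expect_lt(sep$p, 0.05)
  expect_equal(compare_groups(rep(5, 3), rep(5, 4)), list(t = 0, p = 1, df = NA_real_))
})

test_that("compare_groups agrees with a permutation oracle", {
  # pooled-variance t statistic permuted 1e5 times; the t-reference p-value
  # should agree within Monte-Carlo + t-approximation error (~0.03)
  set.seed(12)
  for (rep in 1:3) {
    a <- stats::rnorm(8, 0, 1)
    b <- stats::rnorm(9, 0.8, 1)
    got <- compare_groups(a, b, var_equal = TRUE)$p
    z <- c(a, b)
    n1 <- length(a); n <- length(z)
    B <- 1e5
    tstat <- function(g1, g2) {
      sp <- sqrt(((length(g1) - 1) * stats::var(g1) +
                    (length(g2) - 1) * stats::var(g2)) / (length(g1) + length(g2) - 2))
      (mean(g1) - mean(g2)) / (sp * sqrt(1 / length(g1) + 1 / length(g2)))
    }
    t_obs <- tstat(a, b)
    # vectorised permutation: group-1 membership per shuffle as a 0/1 matrix
    pick <- vapply(seq_len(B), function(i) {
      m <- logical(n); m[sample.int(n, n1)] <- TRUE; m
    }, logical(n))                               # n x B
    s1 <- crossprod(pick, z)[, 1]                # group-1 sums
    q1 <- crossprod(pick, z^2)[, 1]
    s2 <- sum(z) - s1; q2 <- sum(z^2) - q1
    n2 <- n - n1
    v1 <- (q1 - s1^2 / n1) / (n1 - 1)
    v2 <- (q2 - s2^2 / n2) / (n2 - 1)
    sp <- sqrt(((n1 - 1) * v1 + (n2 - 1) * v2) / (n - 2))
    t_perm <- (s1 / n1 - s2 / n2) / (sp * sqrt(1 / n1 + 1 / n2))
    p_perm <- mean(abs(t_perm) >= abs(t_obs))
    expect_equal(got, p_perm, tolerance = 0.03)
  }
})

test_that("recovered cohort mean tracks the configured ONL thickness", {
  # monotonicity: thicker configured ONL -> thicker recovered mean
  means <- c(55, 65, 75)
  rec <- vapply(means, function(m) {
    sim <- gen_oct_volume(small_linescan(seed = 21, noise_sd = 0,
                                         onl_mean = m, onl_sd = 0,
                                         total_sd = 0, rosettes = c(all = 0)))
    seg <- segment_volume(sim$volume)
    mean(seg$onl_plus_um[seg$quality_flag == "ok"])
  }, numeric(1))
  expect_true(all(diff(rec) > 0))
  expect_equal(rec, means, tolerance = 0.03)
})

test_that("cohort-mean recovery stays within 2 SEM of the configured mean", {
  # scaled-down version of the 35-eye parameter-recovery property:
  # 4 seeds x 10 eyes; between-eye SD 5.4 um
  hits <- 0L
  n_eyes <- 10L
  for (s in 1:4) {
    eye_means <- numeric(n_eyes)
    for (e in seq_len(n_eyes)) {
      draw <- with_seed_r(1000 * s + e, stats::rnorm(1, 66.4, 5.4))
      sim <- gen_oct_volume(small_linescan(seed = 1000 * s + e,
                                           noise_sd = 0.02,
                                           onl_mean = draw, onl_sd = 5.4,
                                           rosettes = c(all = 0)))
      seg <- segment_volume(sim$volume)
      prof <- exclude_regions(profile_from_segmentation(seg, "onl_plus"))
      eye_means[e] <- mean(prof$value_um[prof$mask])
    }
    sem <- 5.4 / sqrt(n_eyes)
    if (abs(mean(eye_means) - 66.4) <= 2 * sem) hits <- hits + 1L
  }
  expect_gte(hits, 3L)
})
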