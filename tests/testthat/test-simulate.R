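# helper: FWHM of a 1-D profile by linear interpolation around the peak
profile_fwhm <- function(p) {
  i <- which.max(p)
  half <- p[i] / 2
  left <- i; while (left > 1 && p[left - 1] > half) left <- left - 1
  right <- i; while (right < length(p) && p[right + 1] > half) right <- right + 1
  xl <- if (left == 1) left else
    (left - 1) + (half - p[left - 1]) / (p[left] - p[left - 1])
  xr <- if (right == length(p)) right else
    right + (p[right] - half) / (p[right] - p[right + 1])
  xr - xl
}

test_that("the default LEHR geometry gives the 7.5 mm system resolution", {
  expect_equal(system_resolution_fwhm(), 7.5, tolerance = 0.3 / 7.5)
  # at the collimator face with no intrinsic blur the resolution is the
  # hole diameter
  face <- collimator_spec(source_distance_mm = 0, intrinsic_fwhm_mm = 0,
                          gap_mm = 0)
  expect_equal(system_resolution_fwhm(face), 1.5, tolerance = 1e-12)
  # resolution degrades strictly with distance
  r <- vapply(c(50, 100, 200), function(b)
    system_resolution_fwhm(collimator_spec(source_distance_mm = b)),
    numeric(1))
  expect_true(all(diff(r) > 0))
  expect_error(collimator_spec(hole_diameter_mm = -1), "positive")
})

test_that("projection preserves counts when nothing attenuates or blurs", {
  d <- c(17L, 17L, 17L)
  P <- make_projector(d, 4.42, angles_deg = seq(0, 330, by = 30),
                      psf_fwhm_mm = 0, mu = NULL)
  expect_true(all(forward_project(array(0, d), P)$counts == 0))
  set.seed(2)
  act <- array(0, d)
  act[7:11, 7:11, 7:11] <- runif(125)     # interior blob
  ps <- forward_project(act, P)
  totals <- apply(ps$counts, 3, sum)
  # bilinear rotation conserves mass up to interpolation error
  expect_equal(totals, rep(sum(act), 12), tolerance = 0.02)
  expect_true(all(ps$counts >= 0))
})

test_that("central-ray attenuation matches the analytic path length", {
  d <- c(33L, 33L, 33L)
  vox <- 4.42
  cyl <- outer((1:33) - 17, (1:33) - 17,
               function(y, x) y^2 + x^2 <= 10^2)
  mu <- array(rep(as.vector(cyl), each = 33) * 0.0155, d)
  act <- array(0, d); act[17, 17, 17] <- 1
  P <- make_projector(d, vox, angles_deg = c(0, 90, 180, 270),
                      psf_fwhm_mm = 0, mu = mu)
  totals <- apply(forward_project(act, P)$counts, 3, sum)
  # centre voxel to the rim: ten full voxels plus half the source voxel
  expected <- exp(-0.0155 * vox * 10.5)
  expect_equal(totals, rep(expected, 4), tolerance = 0.02)
})

test_that("back projection is the exact adjoint of forward projection", {
  d <- c(16L, 16L, 16L)
  set.seed(8)
  mu <- gauss_blur3d(array(runif(prod(d)) * 0.02, d), 2)
  P <- make_projector(d, 4.42, angles_deg = seq(0, 300, by = 60),
                      psf_fwhm_mm = 7.5, mu = mu)
  for (i in 1:3) {
    x <- array(runif(prod(d)), d)
    y <- array(runif(d[1] * d[3] * 6), c(d[1], d[3], 6))
    ax_y <- sum(forward_project(x, P)$counts * y)
    x_aty <- sum(x * Reduce(`+`, lapply(1:6, function(k)
      thyroseg:::backproject_one(P, y[, , k], k))))
    expect_equal(ax_y, x_aty, tolerance = 1e-10)
  }
})

test_that("count scaling hits the target mean and noise is reproducible", {
  d <- c(17L, 17L, 17L)
  act <- array(0, d); act[6:12, 6:12, 6:12] <- 5
  P <- make_projector(d, 4.42, angles_deg = seq(0, 354, by = 6),
                      psf_fwhm_mm = 7.5, mu = NULL)
  ps <- forward_project(act, P)
  noisy <- scale_and_add_noise(ps, 1e5, seed = 42)
  totals <- apply(noisy$counts, 3, sum)
  expect_equal(mean(totals), 1e5, tolerance = 0.01)
  expect_true(all(noisy$counts == round(noisy$counts)))
  expect_true(noisy$noise_applied)
  again <- scale_and_add_noise(ps, 1e5, seed = 42)
  expect_identical(noisy$counts, again$counts)
  other <- scale_and_add_noise(ps, 1e5, seed = 43)
  expect_false(identical(noisy$counts, other$counts))
  expect_error(scale_and_add_noise(noisy, 1e5, 1), "already")
  expect_error(scale_and_add_noise(ps, -5, 1), "positive")
})

test_that("OSEM leaves a self-consistent estimate unchanged and guards zeros", {
  d <- c(16L, 16L, 16L)
  P <- make_projector(d, 4.42, angles_deg = seq(0, 300, by = 60),
                      psf_fwhm_mm = 0, mu = NULL)
  est0 <- array(1, d)
  ps <- forward_project(est0, P)
  rec <- osem_reconstruct(ps, P, subsets = 2L, iterations = 3L)
  # interior voxels seen by every ray stay at the fixed point
  core <- rec$values[5:12, 5:12, 5:12]
  expect_equal(core, array(1, dim(core)), tolerance = 1e-6)
  expect_true(all(rec$values >= 0))
  zero <- ps; zero$counts[] <- 0
  expect_warning(rz <- osem_reconstruct(zero, P, 2L, 2L), "all-zero")
  expect_true(all(rz$values == 0))
  expect_error(osem_reconstruct(ps, P, subsets = 7L), "divisible")
})

test_that("a reconstructed point source comes out at the system resolution", {
  d <- c(32L, 32L, 32L)
  vox <- 4.42
  act <- array(0, d); act[16, 16, 16] <- 100
  Psim <- make_projector(d, vox, psf_fwhm_mm = 7.5, mu = NULL)
  ps <- forward_project(act, Psim)
  Prec <- make_projector(d, vox, psf_fwhm_mm = 0, mu = NULL)
  rec <- osem_reconstruct(ps, Prec, subsets = 6L, iterations = 12L)
  pk <- which(rec$values == max(rec$values), arr.ind = TRUE)[1, ]
  fw <- c(profile_fwhm(rec$values[, pk[2], pk[3]]),
          profile_fwhm(rec$values[pk[1], , pk[3]]),
          profile_fwhm(rec$values[pk[1], pk[2], ])) * vox
  expect_true(all(abs(fw - 7.5) < vox))
})

test_that("the fast surrogate blurs, adds calibrated counts and reproduces", {
  ph <- place_hotspot(build_phantom(20, grid = c(64L, 64L, 64L)), 0.1)
  am <- compose_activity(ph, case_spec(20, 0.10, 1.5))
  expect_true(all(degrade_fast(zero_activity(am), noise_scale = 5,
                               seed = 1)$values == 0))
  r1 <- degrade_fast(am, noise_scale = 5, seed = 7)
  r2 <- degrade_fast(am, noise_scale = 5, seed = 7)
  expect_identical(r1$values, r2$values)
  expect_equal(r1$provenance, "surrogate")
  expect_true(all(r1$values >= 0))
  # the noise-free limit approaches the (split) blurred activity map
  sig <- 7.5 / (2 * sqrt(2 * log(2))) / am$voxel_mm
  blurred <- gauss_blur3d(gauss_blur3d(am$values, sig * sqrt(0.5)),
                          sig * sqrt(0.5))
  r3 <- degrade_fast(am, noise_scale = 1e7, seed = 7)
  expect_lt(max(abs(r3$values - blurred)), 0.02)
})

test_that("noise calibration reaches the target CoV and rejects impossible ones", {
  ph <- place_hotspot(build_phantom(20, grid = c(64L, 64L, 64L)), 0.1)
  am <- compose_activity(ph, case_spec(20, 0.20, 1.0))
  # CoV falls as the count scale rises (valid bisection bracket)
  c_lo <- background_cov(degrade_fast(am, noise_scale = 2, seed = 3), ph)
  c_hi <- background_cov(degrade_fast(am, noise_scale = 200, seed = 3), ph)
  expect_gt(c_lo, c_hi)
  ns <- calibrate_noise(am, target_cov = 0.5, seed = 3)
  cov <- background_cov(degrade_fast(am, noise_scale = ns, seed = 3), ph)
  expect_lt(abs(cov - 0.5), 0.05)
  expect_error(calibrate_noise(am, target_cov = 1e-9, seed = 3), "bracket")
  expect_error(calibrate_noise(am, target_cov = 0), "target_cov")
})
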