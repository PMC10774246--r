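test_that("histogram normalizes to one and maps values to the right bins", {
  q <- as_quantized(array(0, c(4, 4, 4)))
  h <- histogram_256(q)
  expect_equal(h$p[1], 1)
  expect_equal(sum(h$p), 1)
  v <- array(c(rep(0, 32), rep(255, 32)), c(4, 4, 4))
  h2 <- histogram_256(as_quantized(v))
  expect_equal(h2$p[1], 0.5)
  expect_equal(h2$p[256], 0.5)
  set.seed(1)
  h3 <- histogram_256(as_quantized(array(sample(0:255, 1000, TRUE), c(10, 10, 10))))
  expect_equal(sum(h3$p), 1)
  expect_error(histogram_256(array(300, c(2, 2, 2))), "0..255")
})

test_that("Otsu matches the independent between-class brute-force oracle", {
  set.seed(101)
  for (i in 1:200) {
    h <- random_histogram(sample(3:200, 1))
    expect_equal(otsu_threshold(h)$threshold, otsu_bruteforce(h$p))
  }
})

test_that("within-class plus between-class variance equals total variance", {
  set.seed(5)
  for (i in 1:20) {
    h <- random_histogram(60)
    res <- otsu_threshold(h)
    lev <- 0:255
    mu <- sum(h$p * lev)
    total <- sum(h$p * (lev - mu)^2)
    for (t in c(1, 50, 128, 200, 255, res$threshold)) {
      wb <- sum(h$p[1:t]); wf <- 1 - wb
      mu_b <- if (wb > 0) sum(h$p[1:t] * lev[1:t]) / wb else 0
      mu_f <- if (wf > 0) (mu - wb * mu_b) / wf else 0
      between <- wb * (mu_b - mu)^2 + wf * (mu_f - mu)^2
      expect_equal(res$sigma_w2_curve[t] + between, total, tolerance = 1e-9)
    }
  }
})

test_that("Otsu tie-break picks the smallest minimizing threshold", {
  p <- numeric(256); p[51] <- 0.5; p[201] <- 0.5   # levels 50 and 200
  h <- structure(list(p = p, n_voxels = 100L), class = "intensity_histogram")
  res <- otsu_threshold(h)
  expect_equal(res$threshold, 51)
  expect_equal(res$sigma_w2, 0)
  expect_error(otsu_threshold(structure(list(p = c(1, numeric(255)),
                                             n_voxels = 1L),
                                        class = "intensity_histogram")),
               "degenerate")
})

test_that("Otsu agrees with EBImage on random 8-bit images", {
  skip_if_not_installed("EBImage")
  set.seed(9)
  for (i in 1:5) {
    v <- c(pmin(pmax(round(rnorm(4000, 60, 20)), 0), 255),
           pmin(pmax(round(rnorm(1000, 180, 25)), 0), 255))
    q <- as_quantized(array(v, c(10, 20, 25)))
    t_pkg <- otsu_threshold(histogram_256(q))$threshold
    t_ebi <- EBImage::otsu(EBImage::Image(matrix(q$values / 255, 100)),
                           range = c(0, 1), levels = 256) * 255
    expect_lte(abs(t_pkg - t_ebi), 1)
  }
})

test_that("Otsu segmentation of a two-level image recovers the bright object", {
  q <- two_level_volume()
  m <- otsu_segment(q)
  expect_identical(m$mask, q$values == 255L)
  expect_equal(m$volume_ml, sum(q$values == 255L) * 4.42^3 / 1000)
})

test_that("Otsu segmentation is invariant to sub-threshold intensity shifts", {
  q <- two_level_volume(lo = 10L, hi = 240L)
  m1 <- otsu_segment(q)
  q2 <- q; q2$values <- q$values + 5L    # shift below the threshold gap
  m2 <- otsu_segment(q2)
  expect_identical(m1$mask, m2$mask)
})

test_that("lambda1 follows the printed parameterisation", {
  expect_equal(lambda1_of(0, 0.3), 0)
  expect_equal(lambda1_of(2.5, pi), 2.5)
  expect_equal(lambda1_of(3e-4, 0.3), 3e-4 * sqrt(pi / 0.3))
  expect_error(lambda1_of(1, 0), "tau")
  expect_error(lambda1_of(-1, 1), "non-negative")
})

test_that("ICTM segments a two-level image exactly with the right region means", {
  q <- two_level_volume()
  st <- ictm_segment(q, ictm_config(k = 3e-4))
  expect_true(st$converged)
  expect_identical(st$mask$mask, q$values == 255L)
  expect_equal(st$c1, 255)
  expect_equal(st$c2, 0)
  # a fixed point stays fixed under one more iteration
  st2 <- ictm_segment(q, ictm_config(k = 3e-4, init = st$mask$mask))
  expect_identical(st2$mask$mask, st$mask$mask)
  expect_lte(st2$iterations, 2)
})

test_that("ICTM energy trace is non-increasing on random volumes", {
  set.seed(23)
  for (i in 1:5) {
    v <- gauss_blur3d(array(runif(16^3) * 255, c(16, 16, 16)), 1.5)
    q <- as_quantized(v)
    st <- tryCatch(ictm_segment(q, ictm_config(k = 10^runif(1, -4, -1))),
                   error = function(e) NULL)
    if (is.null(st)) next   # collapse on a degenerate draw is a valid error
    expect_true(all(diff(st$energy) <= 1e-8 * abs(st$energy[1])))
  }
})

test_that("both segmenters commute with grid flips", {
  q <- two_level_volume(c(20L, 20L, 20L))
  set.seed(4)
  noise <- array(as.integer(round(runif(8000) * 40)), dim(q$values))
  q$values <- q$values + noise
  q$values[q$values > 255L] <- 255L
  flip <- function(a) a[rev(seq_len(dim(a)[1])), , ]
  qf <- q; qf$values <- flip(q$values)
  expect_identical(flip(otsu_segment(q)$mask), otsu_segment(qf)$mask)
  cfg <- ictm_config(k = 1e-3)
  m <- ictm_segment(q, cfg)$mask$mask
  mf <- ictm_segment(qf, cfg)$mask$mask
  expect_identical(flip(m), mf)
})

test_that("ICTM rejects degenerate input and reports collapse", {
  expect_error(ictm_segment(as_quantized(array(7, c(8, 8, 8)))), "degenerate")
  # huge lambda2 forces the mask to swallow everything -> collapse error
  q <- two_level_volume()
  expect_error(ictm_segment(q, ictm_config(k = 1e9, lambda2 = 0)), "collapsed")
})

test_that("k selection finds the plateau of a k-insensitive image", {
  q <- two_level_volume()
  grid_k <- 10^seq(-4, -1, by = 0.5)
  sel <- select_k(q, grid_k, ictm_config())
  expect_equal(nrow(sel$curve), length(grid_k))
  expect_gte(length(sel$plateau), 2)
  true_vol <- sum(q$values == 255L) * 4.42^3 / 1000
  expect_equal(sel$curve$volume_ml[sel$plateau],
               rep(true_vol, length(sel$plateau)))
  expect_true(sel$k %in% grid_k)
  one <- select_k(q, 3e-4, ictm_config())
  expect_equal(one$k, 3e-4)
})
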