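test_that("DSC identities hold", {
  a <- array(FALSE, c(6, 6, 6)); a[2:4, 2:4, 2:4] <- TRUE
  expect_equal(dsc(a, a), 1)
  b <- array(FALSE, c(6, 6, 6)); b[5:6, 5:6, 5:6] <- TRUE
  expect_equal(dsc(a, b), 0)
  # |truth| = 10, |mask| = 10, overlap 5 -> 0.5
  tr <- array(FALSE, c(20, 1, 1)); tr[1:10, 1, 1] <- TRUE
  ms <- array(FALSE, c(20, 1, 1)); ms[6:15, 1, 1] <- TRUE
  expect_equal(dsc(ms, tr), 0.5)
  # conventions for empty masks
  e <- array(FALSE, c(6, 6, 6))
  expect_equal(dsc(e, e), 1)
  expect_equal(dsc(a, e), 0)
  expect_error(dsc(a, array(TRUE, c(2, 2, 2))), "grid")
})

test_that("DSC is symmetric and equals 2J/(1+J) for random masks", {
  set.seed(42)
  for (i in 1:20) {
    a <- array(stats::runif(512) < 0.3, c(8, 8, 8))
    b <- array(stats::runif(512) < 0.3, c(8, 8, 8))
    expect_equal(dsc(a, b), dsc(b, a))
    j <- sum(a & b) / sum(a | b)
    expect_equal(dsc(a, b), 2 * j / (1 + j))
  }
})

test_that("volume summaries match the hand-evaluated error formulas", {
  rec <- data.frame(method = "otsu", volume_ml = c(10, 10),
                    est_volume_ml = c(11, 9))
  s <- summarize_records(rec)
  pooled <- s[s$group == "10-10", ]
  expect_equal(pooled$mae_pct, 10)
  expect_equal(pooled$mrv, 1.0)
  expect_equal(pooled$sd, sqrt(2 * 0.01 / 1), tolerance = 1e-12)
  # exact estimates give zero error
  rec2 <- data.frame(method = "otsu", volume_ml = c(20, 20, 35, 35),
                     est_volume_ml = c(20, 20, 35, 35))
  s2 <- summarize_records(rec2)
  expect_true(all(s2$mae_pct == 0) && all(s2$mrv == 1) &&
                all(s2$sd[s2$group == "20-35"] == 0))
  expect_error(summarize_records(
    data.frame(method = "x", volume_ml = 20, est_volume_ml = 21)), "2 records")
})

test_that("summaries are invariant under record re-ordering", {
  set.seed(7)
  rec <- data.frame(method = "m", volume_ml = rep(c(20, 35), each = 6),
                    est_volume_ml = rep(c(20, 35), each = 6) * runif(12, .8, 1.2))
  s1 <- summarize_records(rec)
  s2 <- summarize_records(rec[sample(12), ])
  expect_equal(s1, s2, ignore_attr = TRUE)
})

test_that("paired t-test matches the textbook formula and handles degeneracy", {
  a <- c(2, 4, 6, 8); b <- c(1, 2, 3, 4)   # differences 1,2,3,4
  r <- paired_t(a, b)
  expect_equal(r$t, 2.5 / (sd(c(1, 2, 3, 4)) / 2), tolerance = 1e-12)
  expect_equal(r$t, 3.872983, tolerance = 1e-6)
  expect_equal(r$p, 2 * pt(-r$t, df = 3), tolerance = 1e-12)
  expect_equal(r$p, 0.03047, tolerance = 1e-3)
  same <- c(0.9, 0.8, 0.7)
  expect_equal(paired_t(same, same), list(t = 0, p = 1, df = 2, mean_diff = 0))
  expect_warning(r0 <- paired_t(c(1, 1), c(0, 0)), "zero variance")
  expect_equal(r0$p, 0)
})

test_that("paired t-test detects a constant shift as n grows", {
  set.seed(11)
  x <- runif(48, 0.7, 0.95)
  y <- pmin(x + 0.02 + rnorm(48, 0, 0.01), 1)
  expect_lt(paired_t(y, x)$p, 0.01)
  expect_gt(paired_t(y, x)$mean_diff, 0)
})

test_that("misclassification projections count missed and false voxels", {
  tr <- array(FALSE, c(10, 10, 10)); tr[4:6, 4:6, 4:6] <- TRUE
  m <- misclass_projection(tr, tr)
  expect_true(all(m$missed == 0) && all(m$false_positive == 0))
  dil <- dilate3d(tr, 1)
  m2 <- misclass_projection(dil, tr, axis = 2)
  expect_true(all(m2$missed == 0))
  expect_equal(sum(m2$false_positive), sum(dil) - sum(tr))
  expect_equal(dim(m2$false_positive), c(10, 10))
  # set identity: missed + false + intersection = union
  set.seed(3)
  a <- array(runif(1000) < 0.4, c(10, 10, 10))
  b <- array(runif(1000) < 0.4, c(10, 10, 10))
  m3 <- misclass_projection(a, b)
  expect_equal(sum(m3$missed) + sum(m3$false_positive) + sum(a & b),
               sum(a | b))
  expect_error(misclass_projection(a, b, axis = 4), "axis")
})
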