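# Shared toy design: K = 2, N = 4, proportion columns
# (0.8,0.2), (0.6,0.4), (0.4,0.6), (0.2,0.8).
toy_h <- function() {
  h <- rbind(c(0.8, 0.6, 0.4, 0.2), c(0.2, 0.4, 0.6, 0.8))
  dimnames(h) <- list(c("C1", "C2"), paste0("s", 1:4))
  h
}

test_that("the proportion-design OLS fit recovers exact cell-type means", {
  h <- toy_h()
  y <- rbind(g1 = 5 * h[1, ] + 1 * h[2, ],    # exact model, means (5, 1)
             g2 = rep(3, 4))                  # constant feature
  fit <- fit_celltype_means(y, h)
  expect_equal(unname(fit$beta["g1", ]), c(5, 1), tolerance = 1e-10)
  expect_equal(unname(fit$beta["g2", ]), c(3, 3), tolerance = 1e-10)
  expect_equal(unname(fit$sigma2_raw), c(0, 0), tolerance = 1e-20)
  expect_identical(fit$df, 2L)
})

test_that("the fit rejects invalid designs", {
  h <- toy_h()
  y <- matrix(1, 1, 4)
  hbad <- h; hbad[, 1] <- c(0.7, 0.2)         # column sums to 0.9
  expect_error(fit_celltype_means(y, hbad), "sum to 1")
  expect_error(fit_celltype_means(y[, 1:2, drop = FALSE], h[, 1:2]),
               "degrees of freedom")
  hrank <- rbind(rep(0.5, 4), rep(0.5, 4))    # rank-deficient design
  expect_error(fit_celltype_means(y, hrank), "rank deficient")
})

test_that("the variance floor follows the interpolated-quantile convention", {
  fl <- variance_floor(1:10, q = 0.10)
  expect_equal(fl$floor_value, 1.9)           # 1 + 0.1 * 9 interpolation
  expect_equal(fl$sigma2_floored, c(1.9, 2:10))

  # equal inputs are unchanged
  fl2 <- variance_floor(rep(4, 5))
  expect_equal(fl2$floor_value, 4)
  expect_equal(fl2$sigma2_floored, rep(4, 5))

  # all-zero input falls back to the epsilon floor
  fl3 <- variance_floor(rep(0, 8))
  expect_equal(fl3$floor_value, 1e-12)
  expect_true(all(fl3$sigma2_floored == 1e-12))

  expect_error(variance_floor(c(1, -0.1)), "negative")
})

test_that("floor dominance: shrinking sub-floor variances changes nothing", {
  s2 <- as.numeric(1:100)
  fl <- variance_floor(s2)
  s2b <- s2; s2b[5] <- 1e-4                   # already below the floor
  flb <- variance_floor(s2b)
  expect_equal(flb$floor_value, fl$floor_value)
  expect_equal(flb$sigma2_floored, fl$sigma2_floored)
})

test_that("one-vs-rest contrasts match a brute-force matrix oracle", {
  h <- toy_h()
  y <- rbind(g1 = 5 * h[1, ] + 1 * h[2, ], g2 = rep(3, 4))
  fit <- fit_celltype_means(y, h)
  fit$sigma2_floored <- rep(0.25, 2)
  res <- test_celltype_contrast(fit, 1)
  expect_equal(res$estimate[1], 4)            # 5 - 1

  # oracle: explicit 2x2 inversion of V'V by the adjugate formula
  v <- t(h)
  xtx <- t(v) %*% v
  inv <- matrix(c(xtx[2, 2], -xtx[2, 1], -xtx[1, 2], xtx[1, 1]), 2, 2) /
    (xtx[1, 1] * xtx[2, 2] - xtx[1, 2] * xtx[2, 1])
  cvec <- c(1, -1)
  se_oracle <- sqrt(0.25 * drop(t(cvec) %*% inv %*% cvec))
  expect_equal(res$se[1], se_oracle, tolerance = 1e-12)
  expect_equal(res$statistic[1], 4 / se_oracle, tolerance = 1e-12)

  # constant feature: null identity (delta = 0, t = 0, p = 1)
  expect_equal(res$estimate[2], 0, tolerance = 1e-12)
  expect_equal(res$statistic[2], 0, tolerance = 1e-10)
  expect_equal(res$p_value[2], 1, tolerance = 1e-10)
})

test_that("contrasts are invariant to relabeling the other cell types", {
  set.seed(51)
  g <- matrix(rgamma(3 * 30, 1), 3, 30)
  h <- sweep(g, 2, colSums(g), "/")
  rownames(h) <- c("C1", "C2", "C3")
  y <- matrix(rnorm(20 * 30, 5), 20, 30)
  t_a <- test_celltype_contrast(fit_celltype_means(y, h), 1)$statistic
  h_swapped <- h[c(1, 3, 2), ]
  t_b <- test_celltype_contrast(fit_celltype_means(y, h_swapped), 1)$statistic
  expect_equal(t_a, t_b, tolerance = 1e-10)
})

test_that("contrast testing requires at least two cell types", {
  h1 <- matrix(1, 1, 5, dimnames = list("C1", paste0("s", 1:5)))
  y <- matrix(rnorm(10 * 5, 3), 10, 5)
  fit <- fit_celltype_means(y, h1)
  expect_error(test_celltype_contrast(fit, 1), "single cell type")
  expect_error(crosscell_test(fit), "single cell type")
})

test_that("null p-values are calibrated and approximately uniform", {
  set.seed(61)
  p <- 10000; n <- 100; k <- 4
  g <- matrix(rgamma(k * n, shape = c(0.968, 4.706, 0.496, 0.347)), k, n)
  h <- sweep(g, 2, colSums(g), "/")
  rownames(h) <- paste0("C", 1:k)
  mu <- runif(p, 2, 8)
  y <- matrix(mu, p, n) + matrix(rnorm(p * n), p, n)   # equal means: null
  d <- crosscell_test(fit_celltype_means(y, h))
  pv <- as.vector(d$p_value)
  frac <- mean(pv < 0.05)
  expect_gt(frac, 0.04)
  expect_lt(frac, 0.06)
  ks <- suppressWarnings(stats::ks.test(pv, "punif"))
  expect_lt(unname(ks$statistic), 0.02)
})

test_that("negative mean estimates are clamped only when enabled", {
  h <- toy_h()
  y <- rbind(g1 = -0.3 * h[1, ] + 2 * h[2, ], g2 = h[1, ] + h[2, ])
  fit <- fit_celltype_means(y, h)
  expect_lt(fit$beta["g1", "C1"], 0)
  same <- bound_negative_means(fit, enabled = FALSE)
  expect_identical(same$beta, fit$beta)
  expect_message(clamped <- bound_negative_means(fit, enabled = TRUE), "clamped")
  expect_identical(clamped$beta["g1", "C1"], 0)
  expect_identical(clamped$beta["g2", ], fit$beta["g2", ])

  # all-non-negative input is unchanged
  fit2 <- fit_celltype_means(rbind(g1 = h[1, ] + h[2, ]), h)
  expect_message(out <- bound_negative_means(fit2, enabled = TRUE), "0 of")
  expect_identical(out$beta, fit2$beta)
})
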