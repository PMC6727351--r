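test_that("variance-window initial features follow the variance ranking", {
  # 10 features with variances increasing in feature index
  n <- 41
  y <- t(sapply(1:10, function(v) sqrt(v) * scale(rnorm(n))[, 1]))
  rownames(y) <- paste0("g", 1:10)
  got <- initial_features(y, "variance", window = c(1, 3))
  expect_identical(got, c("g10", "g9", "g8"))
  expect_identical(initial_features(y, "variance", window = c(4, 6)),
                   c("g7", "g6", "g5"))
  expect_error(initial_features(y, "variance", window = c(1001, 2000)),
               "exceeds")
})

test_that("random initial feature selection is seeded and bounded", {
  y <- matrix(rnorm(200 * 5), 200, 5,
              dimnames = list(paste0("g", 1:200), paste0("s", 1:5)))
  a <- initial_features(y, "random", n_marker = 50, seed = 9)
  b <- initial_features(y, "random", n_marker = 50, seed = 9)
  expect_identical(a, b)
  expect_identical(length(unique(a)), 50L)
  expect_error(initial_features(y, "random", n_marker = 500), "exceeds")
  expect_error(initial_features(y, "random", n_marker = 2, k = 4),
               "at least the number of cell types")
})

test_that("marker selection merges per-type rankings round-robin", {
  # the worked two-type example: p-values per type over six features
  p_mat <- cbind(C1 = c(.001, .2, .3, .4, .5, .6),
                 C2 = c(.5, .002, .003, .6, .7, .8))
  rownames(p_mat) <- paste0("f", 1:6)
  d <- fake_diff(p_mat)
  got <- select_markers(d, n_marker = 4)
  expect_setequal(got, c("f1", "f2", "f3", "f4"))
  expect_identical(got[1:2], c("f1", "f2"))   # round one takes each type's top

  # saturation: n_marker >= P returns all features
  expect_setequal(select_markers(d, n_marker = 10), rownames(p_mat))

  # a feature top-ranked for two types is counted once
  p_shared <- cbind(C1 = c(.001, .5, .6), C2 = c(.002, .7, .8))
  rownames(p_shared) <- paste0("f", 1:3)
  got2 <- select_markers(fake_diff(p_shared), n_marker = 3)
  expect_identical(sort(got2), c("f1", "f2", "f3"))

  expect_error(select_markers(d, n_marker = 1), "at least the number")
})

test_that("marker selection breaks p-value ties by |estimate| then ID", {
  p_mat <- cbind(C1 = c(.01, .01, .01), C2 = c(.9, .9, .9))
  est <- cbind(C1 = c(1, 5, 5), C2 = c(0, 0, 0))
  rownames(p_mat) <- rownames(est) <- c("fa", "fb", "fc")
  got <- select_markers(fake_diff(p_mat, est), n_marker = 2)
  expect_identical(got[1], "fb")              # larger |estimate|, earlier ID
})

test_that("a single-iteration run records baseline and chooses iteration 1", {
  sep <- make_separable(k = 3, m_per = 20, n = 25, seed = 71)
  y <- rbind(sep$y, matrix(5 + rnorm(40 * 25, 0, 0.1), 40, 25,
                           dimnames = list(paste0("x", 1:40),
                                           colnames(sep$y))))
  fit <- decomix(y, k = 3, n_markers = 30, max_iter = 1,
                 init = "variance:1-30", seed = 3)
  expect_identical(fit$trace$iteration, 0:1)
  expect_identical(fit$chosen_iteration, 1L)
  expect_identical(fit$trace$chosen, c(0L, 1L))
  expect_identical(length(fit$features), 30L)
})

test_that("runs are reproducible: identical seeds give identical traces", {
  pp <- default_panel_params(600, 3, n_markers_per_type = 40, seed = 72)
  sim <- simulate_expression_dataset(pp, n = 30, alpha = c(1, 2, 1), seed = 72)
  a <- decomix(sim$mixture, k = 3, n_markers = 120, max_iter = 2,
               init = "variance:121-240", seed = 11)
  b <- decomix(sim$mixture, k = 3, n_markers = 120, max_iter = 2,
               init = "variance:121-240", seed = 11)
  expect_identical(a$trace, b$trace)
  expect_identical(a$proportions, b$proportions)
  expect_identical(a$features_list, b$features_list)
  c <- decomix(sim$mixture, k = 3, n_markers = 120, max_iter = 2,
               init = "variance:121-240", seed = 12)
  expect_false(identical(a$proportions, c$proportions))
})

test_that("the chosen iteration minimizes RMSE among refinement iterations", {
  pp <- default_panel_params(600, 3, n_markers_per_type = 50, seed = 73)
  sim <- simulate_expression_dataset(pp, n = 30, alpha = c(1, 2, 1), seed = 73)
  fit <- decomix(sim$mixture, k = 3, n_markers = 120, max_iter = 4,
                 init = "variance:121-240", seed = 4)
  r <- fit$trace$rmse
  expect_identical(fit$chosen_iteration,
                   which.min(r[-1]))          # baseline excluded from argmin
  expect_true(all(r[fit$chosen_iteration + 1] <= r[-1]))
  expect_equal(fit$rmse, min(r[-1]))
})

test_that("the fitted object supports the standard modelling methods", {
  pp <- default_panel_params(500, 3, n_markers_per_type = 40, seed = 74)
  sim <- simulate_expression_dataset(pp, n = 30, alpha = c(1, 2, 1), seed = 74)
  fit <- decomix(sim$mixture, k = 3, n_markers = 100, max_iter = 2,
                 init = "variance:101-200", seed = 6)
  expect_identical(coef(fit), fit$proportions)
  expect_identical(dim(fitted(fit)), c(100L, 30L))
  expect_identical(dim(residuals(fit)), c(100L, 30L))
  expect_equal(fitted(fit) + residuals(fit), fit$y_chosen, ignore_attr = TRUE)
  pred <- predict(fit, sim$mixture)
  expect_equal(colSums(pred), rep(1, 30), ignore_attr = TRUE)
  expect_output(print(fit), "chosen iteration")
  expect_output(print(summary(fit)), "Iteration trace")
  sims <- simulate(fit, nsim = 2, seed = 1)
  expect_identical(length(sims), 2L)
  expect_true(all(sims[[1]] >= 0))
})

test_that("init specifications parse and invalid ones are rejected", {
  y <- matrix(rnorm(100 * 10), 100, 10,
              dimnames = list(paste0("g", 1:100), paste0("s", 1:10)))
  expect_error(decomix(y, k = 3, init = "nonsense"), "init")
  expect_error(decomix(y, k = 12), "more samples than cell types")
  expect_error(decomix(abs(y), k = 1), "at least 2")
})
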