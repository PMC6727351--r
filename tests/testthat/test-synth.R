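test_that("panel parameter construction is seeded, annotated and bounded", {
  pp <- default_panel_params(200, 4, n_markers_per_type = 10, seed = 3)
  expect_identical(dim(pp$mean), c(200L, 4L))
  expect_identical(sum(!is.na(pp$marker_type)), 40L)
  expect_identical(unname(table(pp$marker_type)), rep(10L, 4L),
                   ignore_attr = TRUE)
  pp2 <- default_panel_params(200, 4, n_markers_per_type = 10, seed = 3)
  expect_identical(pp$mean, pp2$mean)
  expect_identical(pp$marker_type, pp2$marker_type)
  expect_error(default_panel_params(20, 4, n_markers_per_type = 10),
               "cannot plant")

  pm <- default_panel_params(300, 4, n_markers_per_type = 10, effect = 0.4,
                             seed = 4, modality = "methylation")
  expect_true(all(pm$mean >= 0 & pm$mean <= 1))
  expect_true(all(pm$sd >= 0))
})

test_that("a null panel (zero effect) has equal expected marker means", {
  pp <- default_panel_params(100, 3, n_markers_per_type = 5, effect = 0,
                             type_sd = 0, seed = 5)
  expect_equal(pp$mean[, 1], pp$mean[, 2])
  expect_equal(pp$mean[, 1], pp$mean[, 3])
})

test_that("panel estimation from replicates matches hand arithmetic", {
  # 2 features, 2 types, 2 replicates each; log scale for expression
  pure <- cbind(a1 = c(exp(1), exp(3)), a2 = c(exp(2), exp(5)),
                b1 = c(exp(4), exp(1)), b2 = c(exp(6), exp(3)))
  rownames(pure) <- c("g1", "g2")
  pp <- estimate_panel_params(pure, c("A", "A", "B", "B"))
  expect_equal(unname(pp$mean), cbind(c(1.5, 4), c(5, 2)))
  expect_equal(unname(pp$sd), cbind(c(sd(c(1, 2)), sd(c(3, 5))),
                                    c(sd(c(4, 6)), sd(c(1, 3)))))

  # a single-replicate cell type falls back to a pooled scale with a warning
  expect_warning(
    pp1 <- estimate_panel_params(pure[, 1:3], c("A", "A", "B")),
    "single replicate")
  expect_equal(unname(pp1$mean[, 2]), c(4, 1))
  expect_true(all(pp1$sd[, 2] > 0))
  expect_error(estimate_panel_params(pure * 0, c("A", "A", "B", "B")),
               "positive")
})

test_that("zero-noise mixtures are exact panel combinations", {
  pp <- default_panel_params(150, 3, n_markers_per_type = 10, seed = 6)
  sim <- simulate_expression_dataset(pp, n = 12, alpha = c(1, 2, 1),
                                     noise_sd = 0, seed = 6)
  for (s in c(1, 7)) {
    expect_equal(sim$mixture[, s],
                 drop(sim$subject_panels[, , s] %*% sim$h_true[, s]),
                 tolerance = 1e-10, ignore_attr = TRUE)
  }
  expect_equal(colSums(sim$h_true), rep(1, 12), ignore_attr = TRUE)
})

test_that("simulated proportions match Dirichlet moments", {
  pp <- default_panel_params(10, 4, n_markers_per_type = 1, seed = 7)
  alpha <- c(0.968, 4.706, 0.496, 0.347)
  sim <- simulate_expression_dataset(pp, n = 2000, alpha = alpha,
                                     noise_sd = 0, seed = 7,
                                     store_panels = FALSE)
  mean_theory <- alpha / sum(alpha)
  expect_lt(max(abs(rowMeans(sim$h_true) - mean_theory)), 0.01)
  var_theory <- mean_theory * (1 - mean_theory) / (sum(alpha) + 1)
  expect_lt(max(abs(apply(sim$h_true, 1, var) - var_theory) / var_theory),
            0.15)
})

test_that("simulations are bit-reproducible from the seed", {
  pp <- default_panel_params(100, 3, n_markers_per_type = 5, seed = 8)
  a <- simulate_expression_dataset(pp, n = 10, alpha = c(1, 1, 1), seed = 8)
  b <- simulate_expression_dataset(pp, n = 10, alpha = c(1, 1, 1), seed = 8)
  expect_identical(a$mixture, b$mixture)
  expect_identical(a$h_true, b$h_true)
  d <- simulate_expression_dataset(pp, n = 10, alpha = c(1, 1, 1), seed = 9)
  expect_false(identical(a$mixture, d$mixture))
})

test_that("methylation mixtures stay in [0, 1] and accept the 6-type default", {
  pm <- default_panel_params(300, 6, n_markers_per_type = 10, effect = 0.4,
                             seed = 10, modality = "methylation")
  sim <- simulate_methylation_dataset(pm, n = 15, seed = 10)
  expect_true(all(sim$mixture >= 0 & sim$mixture <= 1))
  expect_identical(sim$alpha, c(0.89, 4.12, 0.47, 0.33, 0.61, 1.02))
  expect_identical(attr(sim$mixture, "modality"), "methylation")

  pm5 <- default_panel_params(100, 5, n_markers_per_type = 5, effect = 0.4,
                              seed = 10, modality = "methylation")
  expect_error(simulate_methylation_dataset(pm5, n = 5, seed = 1),
               "supply alpha")
})

test_that("planted markers are recoverable from the expected pure panels", {
  pp <- default_panel_params(2000, 4, n_markers_per_type = 100, seed = 12)
  expected <- exp(pp$mean + pp$sd^2 / 2)        # log-normal means
  got <- true_cts_markers(expected, n = 400)
  planted <- pp$feature_ids[!is.na(pp$marker_type)]
  expect_gte(marker_overlap(got, planted) / length(planted), 0.9)
})

test_that("RNA-seq counts are integer, reproducible negative binomials", {
  sim <- simulate_rnaseq_counts(500, 20, 4, n_true_degs = 100, seed = 13)
  expect_true(all(sim$counts >= 0))
  expect_true(all(sim$counts == round(sim$counts)))
  expect_identical(sum(sim$deg_truth$is_deg), 100L)
  expect_true(all(abs(sim$deg_truth$lfc[sim$deg_truth$is_deg]) >= 0.5))
  sim2 <- simulate_rnaseq_counts(500, 20, 4, n_true_degs = 100, seed = 13)
  expect_identical(sim$counts, sim2$counts)
  expect_error(simulate_rnaseq_counts(500, 20, 4, 100, dispersion = 0),
               "dispersion")
  expect_error(simulate_rnaseq_counts(500, 20, 4, 600), "exceeds")
})

test_that("without planted DEGs the contrast test is approximately null", {
  sim <- simulate_rnaseq_counts(3000, 60, 4, n_true_degs = 0, seed = 14)
  yl <- log2_normalize(sim$counts)
  d <- crosscell_test(fit_celltype_means(yl, sim$h_true))
  frac <- mean(d$p_value < 0.05)
  expect_lt(frac, 0.08)
  expect_gt(frac, 0.02)
})
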