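test_that("two-sample statistics match hand-evaluated formulas", {
  expect_equal(two_sample_statistic(c(1, 2, 3), c(1, 2, 3), "pooled_t"), 0)
  expect_equal(two_sample_statistic(c(1, 2, 3), c(10, 11, 12),
                                    "mean_difference"), -9)
  expect_equal(two_sample_statistic(c(1, 2, 3), c(4, 5, 6), "pooled_t"),
               -3.674, tolerance = 5e-4)
  # agree with t.test on random data
  withr::with_seed(1, {
    a <- rnorm(8); b <- rnorm(10, 1)
  })
  expect_equal(two_sample_statistic(a, b, "pooled_t"),
               oracle_stat(a, b, "pooled_t"), tolerance = 1e-12)
  expect_equal(two_sample_statistic(a, b, "welch_t"),
               oracle_stat(a, b, "welch_t"), tolerance = 1e-12)
  expect_error(two_sample_statistic(1, c(1, 2), "pooled_t"), "at least 2")
})

test_that("exhaustive permutation p-values match direct enumeration", {
  tbl <- tibble::tibble(protein_id = "A",
                        s1 = 1, s2 = 2, s3 = 3, s4 = 10, s5 = 11, s6 = 12)
  grp <- tibble::tibble(sample_id = paste0("s", 1:6),
                        group = rep(c("case", "control"), each = 3))
  fit <- permutation_test(tbl, grp, statistic = "mean_difference",
                          mode = "exhaustive")
  # C(6,3) = 20 assignments; only the two extreme splits reach |T| >= 9
  expect_equal(tidy(fit)$p_value, 2 / 20)
  expect_equal(fit$n_eval, 20)

  # random matrices, all three statistics
  withr::with_seed(3, {
    x <- matrix(rnorm(5 * 8), 5, 8)
  })
  tbl2 <- dplyr::bind_cols(tibble::tibble(protein_id = paste0("P", 1:5)),
                           tibble::as_tibble(as.data.frame(x)))
  names(tbl2)[-1] <- paste0("s", 1:8)
  grp2 <- tibble::tibble(sample_id = paste0("s", 1:8),
                         group = rep(c("case", "control"), each = 4))
  for (kind in c("pooled_t", "welch_t", "mean_difference")) {
    fit2 <- permutation_test(tbl2, grp2, statistic = kind,
                             mode = "exhaustive")
    expect_equal(tidy(fit2)$p_value, unname(oracle_exhaustive_p(x, 4, kind)),
                 info = kind)
  }
})

test_that("constant proteins fall back to mean difference with p = 1", {
  tbl <- tibble::tibble(protein_id = c("flat", "var"),
                        s1 = c(5, 1), s2 = c(5, 2),
                        s3 = c(5, 9), s4 = c(5, 8))
  grp <- tibble::tibble(sample_id = paste0("s", 1:4),
                        group = rep(c("case", "control"), each = 2))
  expect_warning(
    fit <- permutation_test(tbl, grp, mode = "exhaustive"),
    "mean-difference"
  )
  res <- tidy(fit)
  expect_equal(res$p_value[res$protein_id == "flat"], 1)
  expect_true(is.na(res$direction[res$protein_id == "flat"]))
})

test_that("Monte-Carlo p-values are seeded, reproducible, and granular", {
  sim <- simulate_study(tiny_design(n_case = 10, n_control = 10,
                                    n_proteins = 20))
  prot <- rollup_proteins(sim$intensities, sim$peptide_map)
  f1 <- permutation_test(prot, sim$groups, n_perm = 500, seed = 9,
                         mode = "montecarlo")
  f2 <- permutation_test(prot, sim$groups, n_perm = 500, seed = 9,
                         mode = "montecarlo")
  expect_identical(tidy(f1), tidy(f2))
  expect_true(all(tidy(f1)$p_value * 500 == round(tidy(f1)$p_value * 500)))
  f3 <- permutation_test(prot, sim$groups, n_perm = 500, seed = 10,
                         mode = "montecarlo")
  expect_false(identical(tidy(f1)$p_value, tidy(f3)$p_value))
  # smoothing bounds p away from 0
  fs <- permutation_test(prot, sim$groups, n_perm = 100, seed = 1,
                         mode = "montecarlo", smoothing = TRUE)
  expect_true(all(tidy(fs)$p_value >= 1 / 101))
})

test_that("auto mode picks exhaustive for small sample spaces", {
  tbl <- tibble::tibble(protein_id = "A", s1 = 1, s2 = 5, s3 = 2, s4 = 7)
  grp <- tibble::tibble(sample_id = paste0("s", 1:4),
                        group = rep(c("case", "control"), each = 2))
  fit <- permutation_test(tbl, grp, statistic = "mean_difference",
                          n_perm = 1000, mode = "auto")
  expect_equal(fit$mode, "exhaustive")
  expect_equal(fit$n_eval, choose(4, 2))
})

test_that("swapping case/control labels negates statistics, keeps p-values", {
  sim <- simulate_study(tiny_design(n_case = 4, n_control = 4,
                                    n_proteins = 12))
  prot <- rollup_proteins(sim$intensities, sim$peptide_map)
  grp_swapped <- dplyr::mutate(
    sim$groups,
    group = ifelse(.data$group == "case", "control", "case")
  )
  f1 <- permutation_test(prot, sim$groups, mode = "exhaustive")
  f2 <- permutation_test(prot, grp_swapped, mode = "exhaustive")
  expect_equal(tidy(f2)$statistic, -tidy(f1)$statistic, tolerance = 1e-10)
  expect_equal(tidy(f2)$p_value, tidy(f1)$p_value)
})

test_that("significance selection and PFER/FDR arithmetic follow their definitions", {
  res <- tibble::tibble(
    protein_id = paste0("P", 1:10),
    p_value = c(0.0005, 0.001, 0.002, rep(0.5, 7)),
    direction = c("over", "under", "over", rep("over", 7))
  )
  sig <- select_significant(res, alpha = 0.001)
  s <- glance(sig)
  expect_equal(s$n_significant, 2)   # p <= alpha, boundary included
  expect_equal(s$n_over, 1)
  expect_equal(s$n_under, 1)
  expect_equal(s$pfer, 10 * 0.001)
  expect_equal(s$fdr_nominal, 0.01 / 2)

  expect_equal(pfer(1422, 0.001), 1.422)
  expect_equal(pfer(0, 0.5), 0)
  expect_equal(pfer(1000, 0.05), 50)
  expect_equal(round(fdr_nominal(pfer(1422, 0.001), 254), 4), 0.0056)
  expect_equal(fdr_nominal(0, 5), 0)
  expect_true(is.na(fdr_nominal(1.422, 0)))
  # nothing significant -> undefined FDR
  none <- select_significant(dplyr::mutate(res, p_value = 0.9), 0.001)
  expect_equal(glance(none)$n_significant, 0)
  expect_true(is.na(glance(none)$fdr_nominal))
  # PFER is linear in alpha and n_tested
  expect_equal(pfer(300, 0.002), 3 * pfer(100, 0.002))
  expect_equal(pfer(100, 0.004), 2 * pfer(100, 0.002))
})

test_that("null data is calibrated: rejection rate tracks alpha", {
  sim <- simulate_study(tiny_design(
    n_case = 10, n_control = 10, n_proteins = 500,
    peptides_per_protein = c(1, 1), n_differential = 0, seed = 77
  ))
  prot <- rollup_proteins(sim$intensities, sim$peptide_map)
  fit <- permutation_test(prot, sim$groups, n_perm = 2000, seed = 5,
                          mode = "montecarlo")
  alpha <- 0.01
  frac <- mean(tidy(fit)$p_value <= alpha)
  se <- sqrt(alpha * (1 - alpha) / 500)
  expect_lt(abs(frac - alpha), 3 * se + 1e-12)
})

test_that("tidy/glance/autoplot provide the broom-style surface", {
  sim <- simulate_study(tiny_design(n_proteins = 10))
  prot <- rollup_proteins(sim$intensities, sim$peptide_map)
  fit <- permutation_test(prot, sim$groups, n_perm = 200, seed = 1)
  expect_s3_class(tidy(fit), "tbl_df")
  expect_named(tidy(fit), c("protein_id", "statistic", "mean_diff",
                            "p_value", "direction"))
  expect_equal(glance(fit)$n_case, 6)
  expect_s3_class(autoplot(fit), "ggplot")
  sig <- select_significant(fit, 0.05)
  expect_s3_class(glance(sig), "tbl_df")
  expect_true("significant" %in% names(tidy(sig)))
})
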