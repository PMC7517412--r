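null_config <- function(seed, n = 100, ...) {
  cohort_config(n_per_group = n,
                effect_rois = data.frame(roi = integer(), delta = numeric()),
                seed = seed, ...)
}

test_that("BH adjustment matches hand evaluation and brute force", {
  expect_equal(fdr_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(fdr_adjust(rep(0.2, 6)), rep(0.2, 6))
  expect_equal(fdr_adjust(0.37), 0.37)
  set.seed(71)
  for (rep in 1:10) {
    p <- stats::runif(sample(2:20, 1))
    expect_equal(fdr_adjust(p), brute_bh(p), tolerance = 1e-12)
  }
  expect_error(fdr_adjust(c(0.5, 1.2)), class = "fdnet_validation_error")
})

test_that("regional t-tests report Welch statistics, q-values, and direction", {
  cohort <- make_cohort(cohort_config(n_per_group = 40, seed = 19))
  res <- regional_fd_ttests(cohort)
  expect_equal(nrow(res), 68)
  A <- fd_values(cohort, "middle")
  B <- fd_values(cohort, "elderly")
  i <- 67  # a planted-effect region
  tt <- stats::t.test(A[, i], B[, i])
  expect_equal(res$t_statistic[i], unname(tt$statistic), tolerance = 1e-12)
  expect_equal(res$p_value[i], tt$p.value, tolerance = 1e-12)
  expect_equal(res$q_value, fdr_adjust(res$p_value))
  expect_equal(res$direction[i],
               ifelse(mean(B[, i]) < mean(A[, i]), "decrease", "increase"))
})

test_that("identical groups give p = 1 and zero-variance cases are flagged", {
  fd <- matrix(rep(seq(2, 2.3, length.out = 68), each = 6), 6, byrow = FALSE)
  cohort <- fd_cohort(paste0("s", 1:6), rep(c("a", "b"), each = 3),
                      rep(c("F", "M"), 3), fd)
  res <- regional_fd_ttests(cohort)
  expect_true(all(res$p_value == 1))
  expect_true(all(res$degenerate))
  # zero variance, different means: p -> 0, flagged
  fd2 <- fd; fd2[4:6, 1] <- fd2[4:6, 1] + 0.5
  res2 <- regional_fd_ttests(fd_cohort(paste0("s", 1:6),
                                       rep(c("a", "b"), each = 3),
                                       rep(c("F", "M"), 3), fd2))
  expect_equal(res2$p_value[1], 0)
  expect_true(res2$degenerate[1])
})

test_that("null cohorts yield near-zero discovery rates", {
  hits <- vapply(1:8, function(i) {
    res <- regional_fd_ttests(make_cohort(null_config(300 + i, n = 60)))
    mean(res$q_value < 0.05)
  }, 0)
  expect_lte(mean(hits), 0.05)
})

test_that("strong planted shifts are recovered by the regional tests", {
  # d = 1 effects: unambiguous recovery territory for n = 60 per group
  eff <- data.frame(roi = c(3, 17, 40, 61), delta = c(-0.1, -0.1, 0.1, 0.1))
  rec <- vapply(1:5, function(i) {
    co <- make_cohort(cohort_config(n_per_group = 60, effect_rois = eff,
                                    seed = 400 + i))
    res <- regional_fd_ttests(co)
    mean(res$q_value[eff$roi] < 0.05)
  }, 0)
  expect_gte(mean(rec), 0.9)
})

test_that("recovery of the reference-scale deltas rises steeply with smaller region SD", {
  eff <- default_effect_table()
  recovery_at <- function(sd, seeds) {
    mean(vapply(seeds, function(s) {
      co <- make_cohort(cohort_config(n_per_group = 100, roi_sd = sd,
                                      seed = 900 + s))
      mean(regional_fd_ttests(co)$q_value[eff$roi] < 0.05)
    }, 0))
  }
  wide <- recovery_at(0.10, 1:5)
  narrow <- recovery_at(0.04, 1:5)
  expect_lt(wide, 0.3)    # printed deltas vs pooled-scale SD: low power
  expect_gt(narrow, 0.35) # per-region-scale SD: about half recovered
  expect_gt(narrow, 2 * wide)
})

test_that("permutation comparisons are seed-deterministic with valid p-values", {
  cohort <- make_cohort(null_config(23, n = 60))
  a <- permutation_compare(cohort, "Q", n_permutations = 30,
                           per_sex_draw = 15, seed = 99, n_restarts = 4)
  b <- permutation_compare(cohort, "Q", n_permutations = 30,
                           per_sex_draw = 15, seed = 99, n_restarts = 4)
  expect_identical(a$null_distribution, b$null_distribution)
  expect_identical(a$observed_diff, b$observed_diff)
  expect_identical(a$empirical_p, b$empirical_p)
  expect_gte(a$empirical_p, 1 / 31)
  expect_lte(a$empirical_p, 1)
  expect_length(a$null_distribution, 30)
  expect_equal(a$critical_value_95,
               unname(stats::quantile(a$null_distribution, 0.95)))
  c2 <- permutation_compare(cohort, "Q", n_permutations = 30,
                            per_sex_draw = 15, seed = 100, n_restarts = 4)
  expect_false(identical(a$null_distribution, c2$null_distribution))
})

test_that("permutation preconditions are enforced", {
  cohort <- make_cohort(null_config(5, n = 20))
  expect_error(permutation_compare(cohort, "Q", n_permutations = 0,
                                   per_sex_draw = 10),
               class = "fdnet_domain_error")
  expect_error(permutation_compare(cohort, "Q", n_permutations = 10,
                                   per_sex_draw = 11),
               class = "fdnet_domain_error")
  expect_error(permutation_compare(cohort, "nope", n_permutations = 10))
})

test_that("randomized labels are exchangeable on null cohorts", {
  # the two randomized groups' null property samples come from one
  # distribution: KS test should not reject at alpha = 0.01
  cohort <- make_cohort(null_config(31, n = 60))
  pr <- permutation_compare(cohort, "Q", n_permutations = 100,
                            per_sex_draw = 15, seed = 7, n_restarts = 4)
  ks <- suppressWarnings(stats::ks.test(pr$null_a, pr$null_b))
  expect_gt(ks$p.value, 0.01)
  # and lobe-level properties evaluate without error end to end
  pz <- permutation_compare(cohort, "Z_temporal", n_permutations = 5,
                            per_sex_draw = 15, seed = 3, n_restarts = 3)
  expect_true(is.finite(pz$observed_diff))
  pp <- permutation_compare(cohort, "P_total", n_permutations = 5,
                            per_sex_draw = 15, seed = 3, n_restarts = 3)
  expect_true(is.finite(pp$observed_diff))
})
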