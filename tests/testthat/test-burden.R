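test_that("empirical p follows (r+1)/(n+1) and never returns zero", {
  expect_equal(empirical_p(4, 99), 0.05)
  expect_equal(empirical_p(0, 100000), 1 / 100001)
  expect_equal(empirical_p(100, 100), 1)
  expect_error(empirical_p(5, 4), "r")
  r <- sample.int(50, 20)
  expect_true(all(empirical_p(r, 50) > 0 & empirical_p(r, 50) <= 1))
})

make_stats <- function(values, treatments, statistic = "burden") {
  tibble::tibble(
    clone_id = paste0("c", seq_along(values)),
    cell_line = "L1",
    treatment = treatments,
    statistic = statistic,
    value = values)
}

test_that("permutation test matches exhaustive enumeration on 6-clone toys", {
  cmp <- tibble::tibble(group_by_col = "treatment", group_a = "proton",
                        group_b = "control", stratum_col = NA_character_,
                        stratum = "pooled")
  set.seed(33)
  for (rep in 1:5) {
    values <- round(rnorm(6, 10, 4), 1)
    stats <- make_stats(values, rep(c("proton", "control"), each = 3))
    res <- permutation_test(stats, cmp, n_iter = 10000, seed = rep)
    diffs <- exhaustive_perm_oracle(values, 3)
    obs <- mean(values[1:3]) - mean(values[4:6])
    p_exact <- mean(diffs >= obs)
    p_mc <- res$r_ge / res$n_iter
    se <- sqrt(p_exact * (1 - p_exact) / res$n_iter)
    expect_lt(abs(p_mc - p_exact), max(3 * se, 1e-12))
    expect_equal(res$observed_diff, obs)
    expect_equal(res$p_ge, (res$r_ge + 1) / (res$n_iter + 1))
  }
  # all-identical values: both p-values are 1
  res0 <- permutation_test(make_stats(rep(5, 6),
                                      rep(c("proton", "control"), each = 3)),
                           cmp, n_iter = 2000, seed = 1)
  expect_equal(res0$p_ge, 1)
  expect_equal(res0$p_le, 1)
})

test_that("permutation test is deterministic given a seed and uses global shuffles", {
  stats <- tibble::tibble(
    clone_id = paste0("c", 1:9),
    cell_line = rep(c("L1", "L2", "L3"), each = 3),
    treatment = rep(c("control", "helium", "proton"), 3),
    statistic = "burden",
    value = c(1, 5, 7, 2, 6, 9, 1, 4, 8))
  r1 <- permutation_test(stats, n_iter = 500, seed = 99)
  r2 <- permutation_test(stats, n_iter = 500, seed = 99)
  expect_identical(r1, r2)
  # default comparisons include stratified and pooled variants
  expect_true("pooled" %in% r1$stratum)
  expect_true("L1" %in% r1$stratum)
  # observed stratified difference uses only clones of the stratum
  row <- dplyr::filter(r1, comparison == "treatment", group_a == "control",
                       group_b == "helium", stratum == "L1")
  expect_equal(row$observed_diff, 1 - 5)
})

test_that("BH adjustment matches the closed form within families", {
  expect_equal(fdr_adjust(tibble::tibble(p = c(0.01, 0.02, 0.03)))$q,
               c(0.03, 0.03, 0.03))
  expect_equal(fdr_adjust(tibble::tibble(p = 0.04))$q, 0.04)
  expect_equal(fdr_adjust(tibble::tibble(p = c(0.05, 1)))$q, c(0.1, 1))
  set.seed(4)
  p <- runif(40)
  fam <- sample(c("snv", "id", "burden"), 40, replace = TRUE)
  out <- fdr_adjust(tibble::tibble(p = p), family = fam)
  for (f in unique(fam)) {
    expect_equal(out$q[fam == f], bh_oracle(p[fam == f]))
  }
  expect_equal(out$reported, p <= 0.1)
})

test_that("deletion:insertion ratios and SV log2 ratios behave", {
  expect_equal(del_ins_ratio(8, 2, mode = "sv")$log2_ratio, 2)
  expect_equal(del_ins_ratio(5, 5)$ratio, 1)
  expect_equal(del_ins_ratio(655, 89)$ratio, 655 / 89, tolerance = 1e-12)
  expect_true(is.na(del_ins_ratio(3, 0)$ratio))
  expect_equal(del_ins_ratio(3, 0, pseudocount = 1)$ratio, 4)
  expect_error(del_ins_ratio(-1, 2), ">= 0")
})

test_that("length comparisons use a two-sample t-test with degenerate conventions", {
  x <- c(100, 110, 90, 105)
  same <- compare_lengths(x, x)
  expect_equal(same$t, 0)
  expect_equal(same$p, 1)
  set.seed(2)
  a <- rnorm(20, 100, 3)
  b <- rnorm(20, 200, 3)
  expect_lt(compare_lengths(a, b)$p, 0.001)
  ab <- compare_lengths(a, b)
  ba <- compare_lengths(b, a)
  expect_equal(ab$t, -ba$t)
  expect_equal(ab$p, ba$p)
  deg <- compare_lengths(rep(2, 3), rep(2, 4))
  expect_equal(deg$p, 1)
  expect_error(compare_lengths(1, c(1, 2)), ">= 2")
})
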