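test_that("cosine similarity has the right closed-form values and errors", {
  v <- runif(96)
  expect_equal(cosine_similarity(v, v), 1)
  expect_equal(cosine_similarity(c(1, 0, 0), c(0, 1, 0)), 0)
  expect_equal(cosine_similarity(c(1, 1, 0), c(1, 0, 0)), 1 / sqrt(2))
  expect_error(cosine_similarity(c(0, 0), c(1, 1)), "zero")
  expect_error(cosine_similarity(1:3, 1:4), "length")
})

test_that("KL-NMF objective is monotone non-increasing and factors are valid", {
  set.seed(5)
  V <- matrix(rpois(96 * 8, 10), 96, 8)
  fit <- radmut:::nmf_kl(V, k = 3, max_iter = 200, seed = 11)
  expect_true(all(diff(fit$trace) <= 1e-8 * max(1, abs(fit$trace[-1]))))
  expect_true(all(fit$W >= 0))
  expect_true(all(fit$H >= 0))
  expect_equal(colSums(fit$W), rep(1, 3), tolerance = 1e-9)
  expect_error(radmut:::nmf_kl(V, k = 8), "smaller")
  expect_error(radmut:::nmf_kl(matrix(0, 10, 5), k = 2), "all-zero")
})

test_that("noiseless catalogs built as S.E are recovered exactly by rank", {
  sp <- default_sim_spectra()
  E <- matrix(c(3000, 0, 0,
                0, 2500, 0,
                0, 0, 2000,
                1000, 1000, 1000,
                500, 1500, 800), nrow = 3)
  V <- sp %*% E
  colnames(V) <- paste0("cl", 1:5)
  ex <- extract_signatures(V, k_range = 3, n_replicates = 4, seed = 21)
  sim <- radmut:::cosine_matrix(ex$signatures, sp)
  expect_true(all(apply(sim, 2, max) >= 0.99))
  # rank-1 catalog: all clones share one spectrum
  V1 <- sp[, 1, drop = FALSE] %*% matrix(c(1000, 2000, 3000), 1)
  colnames(V1) <- paste0("r", 1:3)
  ex1 <- extract_signatures(V1, k_range = 1, n_replicates = 4, seed = 3)
  expect_gt(cosine_similarity(ex1$signatures[, 1], sp[, 1]), 0.999)
})

test_that("reference assignment respects the 0.85 threshold inclusively and scaling", {
  sp <- default_sim_spectra()
  ref <- sp
  ex <- ref[, 1, drop = FALSE]
  colnames(ex) <- c("X")
  out <- assign_to_reference(ex, ref)
  expect_true(out$assigned)
  expect_equal(out$best_reference, "oxidative_CA")
  expect_equal(out$cosine, 1)
  # scaling invariance
  out2 <- assign_to_reference(ex * 1000, ref)
  expect_equal(out2$cosine, 1)

  # construct spectra with best cosine exactly at / below the threshold
  a <- c(1, rep(0, 95))
  target <- 0.85
  b <- a * target + sqrt(1 - target^2) * c(0, 1, rep(0, 94))
  ref1 <- matrix(a, ncol = 1, dimnames = list(NULL, "R1"))
  exb <- matrix(b, ncol = 1, dimnames = list(NULL, "E"))
  at <- assign_to_reference(exb, ref1, threshold = 0.85)
  expect_equal(at$cosine, 0.85)
  expect_true(at$assigned) # boundary inclusive
  below <- assign_to_reference(exb, ref1, threshold = 0.8501)
  expect_false(below$assigned)
  expect_true(is.na(below$best_reference))

  bad <- ref
  rownames(bad) <- rev(rownames(ref))
  expect_error(assign_to_reference(ex, bad), "category order")
})

test_that("decomposition recovers exact conic combinations and flags poor fits", {
  sp <- default_sim_spectra()
  d <- decompose_signature(0.6 * sp[, 1] + 0.4 * sp[, 2], sp)
  w <- setNames(d$weights$weight, d$weights$reference)
  expect_equal(unname(w["oxidative_CA"]), 0.6, tolerance = 1e-6)
  expect_equal(unname(w["clock_CT"]), 0.4, tolerance = 1e-6)
  expect_equal(d$cosine, 1, tolerance = 1e-9)

  single <- decompose_signature(sp[, 2], sp)
  expect_equal(single$weights$reference, "clock_CT")
  expect_equal(single$weights$weight, 1, tolerance = 1e-9)

  # grid-search oracle: random 2-component mixtures recovered within 1e-6
  set.seed(9)
  for (i in 1:5) {
    wts <- runif(1, 0.2, 0.8)
    pair <- sample(3, 2)
    spec <- wts * sp[, pair[1]] + (1 - wts) * sp[, pair[2]]
    dd <- decompose_signature(spec, sp)
    got <- setNames(dd$weights$weight, dd$weights$reference)
    expect_equal(unname(got[colnames(sp)[pair[1]]]), wts, tolerance = 1e-6)
  }

  # spectrum orthogonal to every reference: poor fit flagged
  ref_sub <- sp
  ref_sub[1, ] <- 0 # remove all weight from one category
  ref_sub <- sweep(ref_sub, 2, colSums(ref_sub), "/")
  onehot <- c(1, rep(0, 95))
  poor <- decompose_signature(onehot, ref_sub)
  expect_true(poor$poor_fit)
  expect_lt(poor$cosine, 1)
  expect_error(decompose_signature(onehot, ref_sub[, 0]), "empty")
})

test_that("signature extraction output is well-formed with exposures refit by NNLS", {
  sp <- default_sim_spectra()
  sim <- simulate_signature_catalog(sp, n_clones = 12,
                                    burden_range = c(1000, 2000), seed = 8)
  ex <- extract_signatures(sim$catalog, k_range = 2:3, n_replicates = 4,
                           seed = 15)
  expect_s3_class(ex, "radmut_signatures")
  expect_equal(colSums(ex$signatures), setNames(rep(1, ex$k),
                                                colnames(ex$signatures)),
               tolerance = 1e-9)
  expect_true(all(ex$signatures >= 0))
  expect_true(all(ex$exposures >= 0))
  # attributed counts approximately conserve per-clone burdens
  tot <- colSums(as_count_matrix(sim$catalog))
  expect_equal(unname(colSums(ex$exposures)), unname(tot), tolerance = 0.05)
  expect_equal(nrow(ex$rank_summary), 2)
  expect_equal(ex$k, 3) # largest qualifying rank under the stability rule
  td <- tidy(ex)
  expect_equal(nrow(td), 96 * ex$k)
  expect_equal(nrow(glance(ex)), 1)
})

test_that("subsampling robustness reports identity when nothing is removed", {
  sp <- default_sim_spectra()
  own <- simulate_signature_catalog(sp, n_clones = 8,
                                    burden_range = c(800, 1200),
                                    seed = 2)$catalog
  rep0 <- subsample_robustness(own, externals = list(), n_repeats = 2,
                               k_range = 3, n_replicates = 3, seed = 77)
  expect_true(all(rep0$report$best_cosine > 1 - 1e-9))

  ext <- simulate_signature_catalog(sp, n_clones = 10,
                                    burden_range = c(800, 1200),
                                    seed = 4)$catalog
  rep_f0 <- subsample_robustness(own, externals = list(ext = ext),
                                 fraction = 0, n_repeats = 1,
                                 k_range = 3, n_replicates = 3, seed = 77)
  expect_true(all(rep_f0$report$best_cosine > 1 - 1e-9))
  expect_error(
    subsample_robustness(own, externals = list(x = ext[, 1, drop = FALSE]),
                         k_range = 3, seed = 1),
    ">= 2")
})
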