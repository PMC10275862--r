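# Small bespoke design used across the simulator tests: one cell line,
# three clones, 1 Mb genome, modest burdens.
small_design <- function() {
  d <- default_design()
  d$layout <- c(chr1 = 1e6)
  d$clones <- d$clones[d$clones$cell_line == "lineA", ][1:4, ] |>
    dplyr::mutate(n_snv = c(150L, 200L, 200L, 220L),
                  n_del = c(20L, 25L, 30L, 30L),
                  n_ins = c(15L, 15L, 15L, 15L))
  d
}

sim_cached <- local({
  env <- new.env()
  function() {
    if (is.null(env$sim)) {
      env$sim <- simulate_cohort(small_design(),
                                 out_dir = file.path(tempdir(), "radmut_sim"),
                                 seed = 424)
    }
    env$sim
  }
})

test_that("toy genomes are deterministic with the requested composition", {
  g1 <- make_toy_genome(c(chr1 = 100000), seed = 1)
  g2 <- make_toy_genome(c(chr1 = 100000), seed = 1)
  expect_identical(g1, g2)
  g3 <- make_toy_genome(c(chr1 = 100000), seed = 2)
  expect_false(identical(g1, g3))
  gc <- sum(strsplit(g1[[1]], "")[[1]] %in% c("G", "C")) / 100000
  expect_lt(abs(gc - 0.41), 0.02)
  g5 <- make_toy_genome(c(chr1 = 50000), gc_fraction = 0.5, seed = 4)
  gc5 <- sum(strsplit(g5[[1]], "")[[1]] %in% c("G", "C")) / 50000
  expect_lt(abs(gc5 - 0.5), 0.02)
  # all 64 trinucleotides present
  tri <- substring(g1[[1]], 1:(100000 - 2), 3:100000)
  expect_equal(length(unique(tri)), 64)
  expect_error(make_toy_genome(c(chr1 = 10)), "1000")
})

test_that("simulated SNVs reproduce the requested spectrum and VAF model", {
  g <- make_toy_genome(c(chr1 = 2e6), seed = 5)
  sp <- default_sim_spectra()
  clone <- default_design()$clones[1, ] |>
    dplyr::mutate(n_snv = 6000L, n_del = 0L, n_ins = 0L, n_sv_del = 0L,
                  n_sv_ins = 0L, n_sv_dup = 0L, n_sv_inv = 0L,
                  exposures = list(c(oxidative_CA = 1, clock_CT = 0,
                                     transition_TC = 0)))
  rec <- simulate_clone(g, clone, seed = 6)
  cls <- classify_snv_96(rec, g)
  # realized truth categories match classification for every SNV
  expect_equal(cls$sbs96, rec$category_true)
  cm <- build_count_matrix(dplyr::mutate(cls, clone_id = "x"), "96")
  realized <- as_count_matrix(cm)[, 1]
  expect_gt(cosine_similarity(realized, sp[, "oxidative_CA"]), 0.99)
  # diploid-het at depth 40: mean VAF within 0.5 +/- 0.01
  expect_lt(abs(mean(rec$alt_reads / rec$depth) - 0.5), 0.01)
})

test_that("injected clusters are recovered as components of the right size", {
  g <- make_toy_genome(c(chr1 = 2e6), seed = 15)
  clone <- default_design()$clones[2, ] |>
    dplyr::mutate(n_snv = 50L, n_del = 0L, n_ins = 0L, n_sv_del = 0L,
                  n_sv_ins = 0L, n_sv_dup = 0L, n_sv_inv = 0L,
                  clusters = list(tibble::tibble(n = 1L, size = 6L,
                                                 span = 3000L)))
  rec <- simulate_clone(g, clone, seed = 16)
  expect_equal(sum(!is.na(rec$cluster_id)), 6)
  cl <- find_clusters(dplyr::filter(rec, var_class == "SNV"))
  big <- dplyr::filter(cl$components, size >= 6)
  expect_equal(nrow(big), 1)
  expect_equal(big$class, "kataegis_like")
  # every injected position lies in the recovered shower (a stray
  # background SNV may occasionally join the component)
  expect_true(all(rec$pos[!is.na(rec$cluster_id)] %in% big$positions[[1]]))
})

test_that("round trip: VCF -> filters recovers exactly the simulated records", {
  sim <- sim_cached()
  cohorts <- read_simulated_cohorts(sim)
  cc <- cohorts[[1]]
  fs <- filter_snvs(cc)
  fi <- filter_indels(cc)
  fv <- filter_svs(cc)
  truth <- sim$truth
  expect_equal(nrow(fs$variants), sum(truth$var_class == "SNV"))
  expect_equal(nrow(fi$variants), sum(truth$var_class %in% c("INS", "DEL")))
  expect_equal(nrow(fv$variants), sum(startsWith(truth$var_class, "SV_")))
  # every contaminant excluded, every truth record retained
  kept <- dplyr::bind_rows(fs$variants, fi$variants, fv$variants)
  key <- function(d) paste(d$chrom, d$pos, d$clone_id)
  expect_setequal(key(kept), key(truth))
  # attribution matches the simulated clone
  expect_equal(sort(unique(kept$clone_id)), sort(sim$design$clones$clone_id))
  # conservation: emitted records = truth + contaminants (the multiallelic
  # contaminant row expands into two per-allele records on reading)
  expect_equal(nrow(sim$contaminants), 10)
  expect_equal(nrow(cc$variants), nrow(truth) + nrow(sim$contaminants) + 1)
})

test_that("round trip classification recovers true categories", {
  sim <- sim_cached()
  genome <- sim$genome
  cc <- read_simulated_cohorts(sim)[[1]]
  snvs <- attributed_variants(filter_snvs(cc))
  cls <- classify_snv_96(snvs, genome)
  truth_snv <- sim$truth |>
    dplyr::filter(var_class == "SNV", !is.na(category_true)) |>
    dplyr::select(chrom, pos, clone_id, category_true)
  joined <- dplyr::inner_join(cls, truth_snv,
                              by = c("chrom", "pos", "clone_id"))
  expect_equal(nrow(joined), nrow(truth_snv))
  expect_equal(mean(joined$sbs96 == joined$category_true), 1)

  indels <- attributed_variants(filter_indels(cc))
  icls <- classify_indel_83(indels, genome)
  truth_id <- sim$truth |>
    dplyr::filter(var_class %in% c("INS", "DEL")) |>
    dplyr::select(chrom, pos, clone_id, category_true)
  ij <- dplyr::inner_join(icls, truth_id, by = c("chrom", "pos", "clone_id"))
  expect_equal(nrow(ij), nrow(truth_id))
  expect_gte(mean(ij$id83 == ij$category_true), 0.99)
})

test_that("cohort simulation is deterministic given the seed", {
  d <- small_design()
  d$layout <- c(chr1 = 3e5)
  d$clones <- d$clones[1:2, ] |>
    dplyr::mutate(n_snv = c(60L, 80L), n_del = c(8L, 8L), n_ins = c(5L, 5L),
                  n_sv_del = 2L, n_sv_ins = 1L, n_sv_dup = 1L, n_sv_inv = 1L)
  s1 <- simulate_cohort(d, out_dir = tempfile("det1"), seed = 31,
                        contaminants = FALSE)
  s2 <- simulate_cohort(d, out_dir = tempfile("det2"), seed = 31,
                        contaminants = FALSE)
  expect_identical(readLines(s1$vcf_paths[[1]]), readLines(s2$vcf_paths[[1]]))
  expect_identical(readLines(s1$genome_path), readLines(s2$genome_path))
  s3 <- simulate_cohort(d, out_dir = tempfile("det3"), seed = 32,
                        contaminants = FALSE)
  expect_false(identical(readLines(s3$vcf_paths[[1]]),
                         readLines(s1$vcf_paths[[1]])))
})
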