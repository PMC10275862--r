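test_that("VCF reading maps FORMAT fields, flags multiallelics, handles empty bodies", {
  path <- write_mini_vcf(c(
    vcf_row(100, s1 = "0/1:20,20:40:60"),
    vcf_row(200, ref = "C", alt = "T,G",
            s1 = "1/2:20,10,10:40:60")
  ))
  cc <- read_cohort_vcf(path, mini_treatments)
  expect_s3_class(cc, "clone_cohort")
  expect_equal(nrow(cc$variants), 3) # 1 + 2 alleles
  ev <- dplyr::filter(cc$evidence, variant_id == "v1", clone_id == "PR1A")
  expect_equal(ev$alt_reads, 20)
  expect_equal(ev$depth, 40)
  expect_true(ev$genotyped)
  expect_false(cc$evidence$genotyped[cc$evidence$variant_id == "v1" &
                                       cc$evidence$clone_id == "PR1B"])
  expect_equal(sum(cc$variants$multiallelic), 2)
  # missing PAF recorded as NA, not defaulted
  expect_true(is.na(cc$variants$pop_af[1]))

  empty <- write_mini_vcf(character(0))
  cc0 <- read_cohort_vcf(empty, mini_treatments)
  expect_equal(nrow(cc0$variants), 0)

  expect_error(read_cohort_vcf(path, c(X = "control")), "samples")
})

test_that("VAF is alt_reads/depth and errors on zero depth", {
  expect_equal(compute_vaf(20, 40), 0.5)
  expect_equal(compute_vaf(10, 40), 0.25)
  expect_equal(compute_vaf(0, 30), 0)
  expect_error(compute_vaf(1, 0), "depth")
  expect_error(compute_vaf(41, 40), "exceed")
})

test_that("SNV cascade applies the six rules with the documented boundaries", {
  path <- write_mini_vcf(c(
    vcf_row(100),                                        # passes all
    vcf_row(200, filter = "LowQual"),                    # rule 1
    vcf_row(300, info = "MAP=0"),                        # rule 2
    vcf_row(400, info = "MAP=1;PAF=0.002"),              # rule 3: 0.2% >= 0.1%
    vcf_row(450, info = "MAP=1;PAF=0.0005"),             # rare: passes
    vcf_row(500, s2 = "0/1:20,20:40:60"),                # rule 4: two clones
    vcf_row(600, alt = "T,G", s1 = "1/2:20,10,10:40:60"),# rule 5
    vcf_row(700, s1 = "0/1:39,1:40:60"),                 # rule 6: 1 read
    vcf_row(800, s1 = "0/1:38,2:40:60")                  # boundary: 2 reads
  ))
  cc <- read_cohort_vcf(path, mini_treatments)
  f <- filter_snvs(cc)
  expect_equal(sort(f$variants$pos), c(100, 450, 800))
  expect_true(all(f$variants$clone_id == "PR1A"))
  expect_true(all(f$variants$vaf >= 2 / 40 & f$variants$vaf <= 1))
})

test_that("indel cascade adds GQ and cross-clone support rules", {
  ind <- function(pos, gq = 60, s2 = "0/0:40,0:40:60",
                  s3 = "0/0:40,0:40:60") {
    vcf_row(pos, ref = "AT", alt = "A",
            s1 = paste0("0/1:20,20:40:", gq), s2 = s2, s3 = s3)
  }
  path <- write_mini_vcf(c(
    ind(100),                     # passes
    ind(200, gq = 9),             # below GQ threshold
    ind(300, gq = 10),            # boundary: retained
    ind(400, s2 = "0/0:39,1:40:60", s3 = "0/0:39,1:40:60"), # 2 others w/ 1 read: kept
    ind(500, s2 = "0/0:38,2:40:60"),                        # 1 other w/ 2 reads: kept
    ind(600, s2 = "0/0:38,2:40:60", s3 = "0/0:38,2:40:60")  # 2 others w/ 2: removed
  ))
  cc <- read_cohort_vcf(path, mini_treatments)
  f <- filter_indels(cc)
  expect_equal(sort(f$variants$pos), c(100, 300, 400, 500))

  # more than two other clones with >= 1 supporting read: needs 4 samples
  samples4 <- c("PR1A", "PR1B", "PR1C", "PR1D")
  row4 <- paste("chr1", 100, ".", "AT", "A", ".", "PASS", "MAP=1",
                "GT:AD:DP:GQ", "0/1:20,20:40:60", "0/0:39,1:40:60",
                "0/0:39,1:40:60", "0/0:39,1:40:60", sep = "\t")
  p4 <- write_mini_vcf(row4, samples = samples4)
  cc4 <- read_cohort_vcf(p4, c(PR1A = "proton", PR1B = "helium",
                               PR1C = "control", PR1D = "control"))
  expect_equal(nrow(filter_indels(cc4)$variants), 0)
})

test_that("SV cascade requires split-read support in the genotyped clone", {
  sv <- function(pos, sr, s2 = "0/0:40,0:40:60:0") {
    vcf_row(pos, ref = "A", alt = "<DEL>",
            info = paste0("MAP=1;SVTYPE=DEL;END=", pos + 5000),
            format = "GT:AD:DP:GQ:SR",
            s1 = paste0("0/1:20,20:40:60:", sr),
            s2 = s2, s3 = "0/0:40,0:40:60:0")
  }
  path <- write_mini_vcf(c(
    sv(1000, 2),                              # boundary: retained
    sv(2000, 1),                              # removed
    sv(3000, 5, s2 = "0/1:20,20:40:60:5")     # two genotyped clones: removed
  ))
  cc <- read_cohort_vcf(path, mini_treatments)
  f <- filter_svs(cc)
  expect_equal(f$variants$pos, 1000)
  expect_equal(f$variants$var_class, "SV_DEL")
})

test_that("filtering is idempotent, subsetting, and rule-monotone", {
  rows <- c(
    vcf_row(100), vcf_row(200, filter = "LowQual"), vcf_row(300, info = "MAP=0"),
    vcf_row(400, info = "MAP=1;PAF=0.01"), vcf_row(500, s2 = "0/1:20,20:40:60"),
    vcf_row(600, alt = "T,G", s1 = "1/2:20,10,10:40:60"),
    vcf_row(700, s1 = "0/1:39,1:40:60"), vcf_row(820), vcf_row(950)
  )
  cc <- read_cohort_vcf(write_mini_vcf(rows), mini_treatments)
  f1 <- filter_snvs(cc)
  f2 <- filter_snvs(f1)
  expect_equal(f1$variants$variant_id, f2$variants$variant_id)
  expect_true(all(f1$variants$variant_id %in% cc$variants$variant_id))
  # dropping any one rule yields a superset of the all-rules output
  all_ids <- f1$variants$variant_id
  for (drop in radmut:::snv_rule_names()) {
    sub <- filter_snvs(cc, rules = setdiff(radmut:::snv_rule_names(), drop))
    expect_true(all(all_ids %in% sub$variants$variant_id), info = drop)
  }
})

test_that("mappability mask and breakend conversion utilities work", {
  path <- write_mini_vcf(c(vcf_row(150), vcf_row(250)))
  cc <- read_cohort_vcf(path, mini_treatments)
  mask <- tibble::tibble(chrom = "chr1", start = 100, end = 200)
  cc2 <- apply_mappability_mask(cc, mask)
  # 1-based 150 -> 0-based 149 inside [100,200); 250 -> 249 outside
  expect_equal(cc2$variants$mappable, c(TRUE, FALSE))

  bnd <- tibble::tibble(
    chrom = c("chr1", "chr1"), pos = c(1000, 2000),
    alt = c("A[chr1:2000[", "T[chr1:1000["),
    id = c("b1", "b2"), mate_id = c("b2", "b1"))
  inv <- convert_breakends_to_inversions(bnd)
  expect_equal(nrow(inv), 1)
  expect_equal(inv$pos, 1000)
  expect_equal(inv$sv_end, 2000)
  expect_equal(inv$var_class, "SV_INV")
})
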