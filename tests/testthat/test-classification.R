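test_that("6-class SNV typing is strand-symmetric and validates bases", {
  expect_equal(classify_snv_6("G", "T"), "C>A")
  expect_equal(classify_snv_6("C", "T"), "C>T")
  expect_equal(classify_snv_6("A", "G"), "T>C")
  # full strand symmetry over all 12 base changes
  bases <- c("A", "C", "G", "T")
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  for (r in bases) for (a in setdiff(bases, r)) {
    expect_equal(classify_snv_6(r, a),
                 classify_snv_6(comp[[r]], comp[[a]]))
  }
  expect_error(classify_snv_6("N", "A"), "non-ACGT")
  expect_error(classify_snv_6("C", "C"), "differ")
})

test_that("SBS96 classification reads context, normalizes strand, checks REF", {
  g <- c(chr1 = "TACATGTTCAG")
  v <- tibble::tibble(chrom = "chr1", pos = c(3L, 9L),
                      ref = c("C", "C"), alt = c("A", "G"))
  out <- classify_snv_96(v, g)
  expect_equal(out$sbs96, c("A[C>A]A", "T[C>G]A"))
  v2 <- tibble::tibble(chrom = "chr1", pos = 5L, ref = "T", alt = "A")
  expect_equal(classify_snv_96(v2, g)$sbs96, "A[T>A]G")
  # purine-strand record folds to the pyrimidine strand: TGT G>T == ACA C>A
  g_pur <- c(chr1 = "GGTGTGG")
  v3 <- tibble::tibble(chrom = "chr1", pos = 4L, ref = "G", alt = "T")
  expect_equal(classify_snv_96(v3, g_pur)$sbs96, "A[C>A]A")
  expect_error(
    classify_snv_96(tibble::tibble(chrom = "chr1", pos = 3L,
                                   ref = "G", alt = "A"), g),
    "does not match REF")
  expect_error(
    classify_snv_96(tibble::tibble(chrom = "chr1", pos = 1L,
                                   ref = "T", alt = "A"), g),
    "flanking")
})

test_that("strand symmetry holds for every SBS96 category on constructed sequences", {
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  rc <- function(s) paste(rev(strsplit(chartr("ACGT", "TGCA", s), "")[[1]]),
                          collapse = "")
  for (cat in sbs96_categories()) {
    up <- substr(cat, 1, 1)
    ref <- substr(cat, 3, 3)
    alt <- substr(cat, 5, 5)
    down <- substr(cat, 7, 7)
    ctx <- paste0(up, ref, down)
    fwd <- c(chrX = paste0("GG", ctx, "GG"))
    lab_fwd <- classify_snv_96(
      tibble::tibble(chrom = "chrX", pos = 4L, ref = ref, alt = alt),
      fwd)$sbs96
    rev_g <- c(chrX = paste0("GG", rc(ctx), "GG"))
    lab_rev <- classify_snv_96(
      tibble::tibble(chrom = "chrX", pos = 4L,
                     ref = comp[[ref]], alt = comp[[alt]]),
      rev_g)$sbs96
    expect_equal(lab_fwd, cat)
    expect_equal(lab_rev, cat)
  }
})

test_that("ID83 classification matches the constructive exemplar for documented cases", {
  # deletion of one T inside a run of six Ts -> 6+ homopolymer bin
  g <- c(chr1 = "ACATTTTTTGACGATT")
  v <- tibble::tibble(chrom = "chr1", pos = 3L, ref = "AT", alt = "A")
  expect_equal(classify_indel_83(v, g)$id83, "1:Del:T:5")
  # insertion of one C next to zero existing Cs
  v <- tibble::tibble(chrom = "chr1", pos = 10L, ref = "G", alt = "GC")
  expect_equal(classify_indel_83(v, g)$id83, "1:Ins:C:0")
  # deletion of CTAG followed immediately by CT -> 2 bp microhomology
  g2 <- c(chr1 = "AAAAACTAGCTGGGG")
  v <- tibble::tibble(chrom = "chr1", pos = 5L, ref = "ACTAG", alt = "A")
  expect_equal(classify_indel_83(v, g2)$id83, "4:Del:M:2")
  # left-normalization: deleting the right A of "AA" equals deleting the left
  g3 <- c(chr1 = "GGCAAGG")
  left <- tibble::tibble(chrom = "chr1", pos = 3L, ref = "CA", alt = "C")
  right <- tibble::tibble(chrom = "chr1", pos = 4L, ref = "AA", alt = "A")
  expect_equal(classify_indel_83(left, g3)$id83,
               classify_indel_83(right, g3)$id83)
  expect_error(classify_indel_83(
    tibble::tibble(chrom = "chr1", pos = 2L, ref = "GC", alt = "G"), g3,
    max_len = 0), "max_len")
})

test_that("the 83-exemplar fixture hits every ID83 category exactly once", {
  fx <- id83_fixture()
  out <- classify_indel_83(fx$variants, fx$genome)
  expect_equal(out$id83, out$expected)
  expect_setequal(out$id83, id83_categories())
  expect_equal(anyDuplicated(out$id83), 0)
})

test_that("SV classification maps classes and computes lengths", {
  v <- tibble::tibble(
    chrom = "chr1", pos = c(1000, 10, 500, 700),
    var_class = c("SV_DEL", "SV_INV", "SV_INS", "SV_INS"),
    sv_end = c(6000, 110, 501, 701),
    ins_len = c(NA, NA, 300, NA))
  out <- classify_sv(v)
  expect_equal(out$sv_class, c("DEL", "INV", "INS", "INS"))
  expect_equal(out$sv_len, c(5000, 100, 300, NA))
  expect_error(classify_sv(tibble::tibble(chrom = "c", pos = 1,
                                          var_class = "SV_FOO",
                                          sv_end = 2)),
               "unknown SV type")
})

test_that("count matrices tally per clone, zero-fill, and collapse 96 -> 6", {
  g <- c(chr1 = "TACATGTTCAGCATTCCGGATC")
  set.seed(42)
  pos <- 2:21
  v <- tibble::tibble(
    chrom = "chr1", pos = pos,
    ref = strsplit(substr(g, 2, 21), "")[[1]],
    clone_id = rep(c("c1", "c2"), 10))
  v$alt <- vapply(v$ref, function(r) sample(setdiff(c("A", "C", "G", "T"), r), 1),
                  character(1))
  cls <- classify_snv_96(v, g)
  cm96 <- build_count_matrix(cls, "96")
  expect_equal(cm96$category, sbs96_categories())
  expect_equal(sum(cm96$c1), 10)
  expect_equal(sum(cm96$c2), 10)
  cm6 <- build_count_matrix(cls, "6")
  expect_equal(as_count_matrix(collapse_96_to_6(cm96)),
               as_count_matrix(cm6))
  # column sums conserved under category reordering
  perm <- sample(nrow(cm96))
  expect_equal(colSums(as_count_matrix(cm96[perm, ])),
               colSums(as_count_matrix(cm96)))
  # empty input with declared clones -> all-zero full category list
  cm0 <- build_count_matrix(cls[0, ], "96", clone_ids = c("c1", "c2"))
  expect_equal(dim(as_count_matrix(cm0)), c(96L, 2L))
  expect_true(all(as_count_matrix(cm0) == 0))
})
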