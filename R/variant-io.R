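#' Read a jointly genotyped multi-sample VCF into a clone cohort
#'
#' One cohort corresponds to one cell line: all clones of that line are
#' samples of a single VCF, jointly genotyped, so that a somatic variant
#' acquired by one clone appears genotyped in that clone only. Each VCF row
#' yields one record per alternate allele; rows with several ALT alleles
#' are flagged `multiallelic`. Missing INFO annotations are recorded as
#' `NA`, never silently defaulted.
#'
#' @param path VCF 4.x file (plain or bgzipped).
#' @param clone_treatments Named character vector mapping VCF sample names
#'   (clone ids) to treatments (`control`, `helium`, `proton`).
#' @param cell_line Cohort label; defaults to the file name.
#' @param format_keys FORMAT field names for allele depth, total depth,
#'   genotype quality and (SVs) alt-supporting split reads.
#' @param info_keys INFO field names for population allele frequency,
#'   mappability (0/1), SV end and SV type.
#' @return Object of class `clone_cohort`: list with `cell_line`, `clones`
#'   (tibble `clone_id`, `treatment`), `variants` (one row per variant
#'   record) and `evidence` (one row per record per clone).
#' @export
read_cohort_vcf <- function(path, clone_treatments, cell_line = NULL,
                            format_keys = list(ad = "AD", dp = "DP",
                                               gq = "GQ", sr = "SR"),
                            info_keys = list(af = "PAF", mappable = "MAP",
                                             end = "END", svtype = "SVTYPE")) {
  if (!file.exists(path)) abort(paste0("cannot read VCF: ", path))
  if (is.null(cell_line)) cell_line <- sub("\\.vcf(\\.gz)?$", "", basename(path))
  vcf <- vcfR::read.vcfR(path, verbose = FALSE)
  samples <- colnames(vcf@gt)[-1]
  if (!setequal(samples, names(clone_treatments))) {
    abort(paste0("VCF samples do not match clone_treatments: VCF has ",
                 paste(samples, collapse = ", ")))
  }
  clones <- tibble(clone_id = samples,
                   treatment = unname(clone_treatments[samples]))

  fix <- as.data.frame(vcf@fix, stringsAsFactors = FALSE)
  n <- nrow(fix)
  if (n == 0) {
    return(new_clone_cohort(cell_line, clones,
                            empty_variants(), empty_evidence()))
  }
  info_vec <- function(key) {
    x <- tryCatch(vcfR::extract.info(vcf, key), error = function(e) NULL)
    if (is.null(x) || length(x) != n) rep(NA_character_, n) else x
  }
  pop_af <- suppressWarnings(as.numeric(info_vec(info_keys$af)))
  map_raw <- suppressWarnings(as.integer(info_vec(info_keys$mappable)))
  sv_end <- suppressWarnings(as.numeric(info_vec(info_keys$end)))
  svtype <- info_vec(info_keys$svtype)

  gt <- vcfR::extract.gt(vcf, "GT")
  ad <- vcfR::extract.gt(vcf, format_keys$ad)
  dp <- suppressWarnings(
    apply(vcfR::extract.gt(vcf, format_keys$dp), 2, as.numeric))
  gq <- suppressWarnings(
    apply(vcfR::extract.gt(vcf, format_keys$gq), 2, as.numeric))
  sr <- tryCatch(suppressWarnings(
    apply(vcfR::extract.gt(vcf, format_keys$sr), 2, as.numeric)),
    error = function(e) matrix(NA_real_, n, length(samples)))
  dim(dp) <- dim(gq) <- dim(sr) <- c(n, length(samples))

  alts <- strsplit(fix$ALT, ",", fixed = TRUE)
  n_alt <- lengths(alts)
  rows <- rep(seq_len(n), n_alt)
  allele <- sequence(n_alt)

  variants <- tibble(
    variant_id = paste0("v", seq_along(rows)),
    chrom = fix$CHROM[rows],
    pos = as.integer(fix$POS[rows]),
    ref = fix$REF[rows],
    alt = unlist(alts),
    caller_pass = fix$FILTER[rows] %in% c("PASS", "."),
    pop_af = pop_af[rows],
    mappable = ifelse(is.na(map_raw[rows]), NA, map_raw[rows] == 1L),
    multiallelic = (n_alt > 1L)[rows],
    sv_end = sv_end[rows]
  )
  variants$var_class <- infer_var_class(variants$ref, variants$alt,
                                        svtype[rows])

  ad_split <- strsplit(ifelse(is.na(ad), "", ad), ",", fixed = TRUE)
  ad_mat <- matrix(ad_split, n, length(samples))
  ev <- list()
  for (s in seq_along(samples)) {
    g <- gt[rows, s]
    alt_reads <- vapply(seq_along(rows), function(i) {
      parts <- ad_mat[[rows[i], s]]
      if (length(parts) < allele[i] + 1L) return(NA_real_)
      suppressWarnings(as.numeric(parts[allele[i] + 1L]))
    }, numeric(1))
    genotyped <- !is.na(g) & g != "." &
      vapply(strsplit(ifelse(is.na(g), "", g), "[/|]"), function(p) {
        any(p != "0" & p != ".")
      }, logical(1))
    ev[[s]] <- tibble(
      variant_id = variants$variant_id,
      clone_id = samples[s],
      alt_reads = alt_reads,
      depth = dp[rows, s],
      genotype_quality = gq[rows, s],
      genotyped = genotyped,
      split_reads = sr[rows, s]
    )
  }
  evidence <- list_rbind(ev)
  bad <- !is.na(evidence$alt_reads) & !is.na(evidence$depth) &
    evidence$alt_reads > evidence$depth
  if (any(bad)) abort("malformed FORMAT fields: alt reads exceed depth")
  new_clone_cohort(cell_line, clones, variants, evidence)
}

infer_var_class <- function(ref, alt, svtype) {
  symbolic <- grepl("^<", alt)
  cls <- character(length(ref))
  sv <- symbolic | (!is.na(svtype) & svtype != "")
  typ <- ifelse(is.na(svtype) | svtype == "",
                sub("^<(.+)>$", "\\1", alt), svtype)
  cls[sv] <- paste0("SV_", typ[sv])
  small <- !sv
  cls[small & nchar(ref) == 1 & nchar(alt) == 1] <- "SNV"
  cls[small & nchar(ref) < nchar(alt)] <- "INS"
  cls[small & nchar(ref) > nchar(alt)] <- "DEL"
  known <- c("SNV", "INS", "DEL", "SV_DEL", "SV_INS", "SV_DUP", "SV_INV",
             "SV_BND")
  if (any(!cls %in% known)) {
    abort(paste0("unrecognized variant class for ALT ",
                 alt[!cls %in% known][1]))
  }
  cls
}

empty_variants <- function() {
  tibble(variant_id = character(0), chrom = character(0), pos = integer(0),
         ref = character(0), alt = character(0), caller_pass = logical(0),
         pop_af = numeric(0), mappable = logical(0),
         multiallelic = logical(0), sv_end = numeric(0),
         var_class = character(0))
}

empty_evidence <- function() {
  tibble(variant_id = character(0), clone_id = character(0),
         alt_reads = numeric(0), depth = numeric(0),
         genotype_quality = numeric(0), genotyped = logical(0),
         split_reads = numeric(0))
}

new_clone_cohort <- function(cell_line, clones, variants, evidence) {
  if (anyDuplicated(clones$clone_id)) abort("duplicate clone ids")
  extra <- setdiff(unique(evidence$clone_id), clones$clone_id)
  if (length(extra)) abort("evidence refers to undeclared clones")
  structure(list(cell_line = cell_line, clones = clones,
                 variants = variants, evidence = evidence),
            class = "clone_cohort")
}

#' @export
print.clone_cohort <- function(x, ...) {
  cat("Clone cohort:", x$cell_line, "\n")
  cat("  clones:", nrow(x$clones), "(",
      paste(x$clones$treatment, collapse = ", "), ")\n")
  cat("  variant records:", nrow(x$variants), "\n")
  tab <- table(x$variants$var_class)
  if (length(tab)) {
    cat("  ", paste(names(tab), tab, sep = ": ", collapse = "; "), "\n")
  }
  if (!is.null(attr(x, "filtered"))) {
    cat("  filtered:", attr(x, "filtered"), "\n")
  }
  invisible(x)
}

#' Variant allele fraction
#'
#' VAF = alt-supporting reads / total depth, the proportion of sequencing
#' reads carrying the variant. In clonally expanded populations VAF peaks
#' reflect ploidy: ~1 for haploid segments, ~0.5 for heterozygous diploid,
#' ~0.25 for heterozygous tetraploid (or a two-cell bottleneck).
#'
#' @param alt_reads,depth Read counts (vectorized); `depth` must be > 0.
#' @return Numeric vector in `[0, 1]`.
#' @export
#' @examples
#' compute_vaf(10, 40) # tetraploid-like peak
compute_vaf <- function(alt_reads, depth) {
  if (any(is.na(depth)) || any(depth <= 0)) {
    abort("VAF undefined: depth must be positive")
  }
  if (any(alt_reads > depth)) abort("alt_reads exceed depth")
  alt_reads / depth
}

#' Mark variant mappability from a BED mask
#'
#' Sets the `mappable` flag of every variant record according to whether
#' its position falls inside a uniquely mappable region given as a BED
#' mask (0-based half-open intervals).
#'
#' @param cohort A `clone_cohort`.
#' @param mask Data frame with `chrom`, `start`, `end` (0-based half-open),
#'   e.g. from [read_bins_bed()].
#' @return The cohort with `mappable` recomputed.
#' @export
apply_mappability_mask <- function(cohort, mask) {
  mask <- as_tibble(mask)
  v <- cohort$variants
  inside <- rep(FALSE, nrow(v))
  p0 <- pos_to_bed(v$pos)
  for (ch in unique(v$chrom)) {
    m <- mask |> filter(.data$chrom == ch) |> arrange(.data$start)
    vi <- which(v$chrom == ch)
    if (nrow(m) == 0) next
    idx <- findInterval(p0[vi], m$start)
    inside[vi] <- idx >= 1 & p0[vi] < m$end[pmax(idx, 1)]
  }
  cohort$variants$mappable <- inside
  cohort
}

#' Convert paired inversion breakends to inversion records
#'
#' SV callers often report inversions as mated breakend (BND) pairs. Two
#' mated breakends on the same chromosome whose bracket orientations are
#' consistent with an inversion (both `t[p[` or both `]p]t`) are merged
#' into one `SV_INV` record spanning min to max breakpoint.
#'
#' @param bnd Tibble with columns `chrom`, `pos`, `alt` (breakend
#'   notation), `id`, `mate_id`.
#' @return Tibble of inversion records (`chrom`, `pos`, `sv_end`,
#'   `var_class = "SV_INV"`, `bnd_ids`).
#' @export
convert_breakends_to_inversions <- function(bnd) {
  bnd <- as_tibble(bnd)
  done <- character(0)
  out <- list()
  for (i in seq_len(nrow(bnd))) {
    if (bnd$id[i] %in% done) next
    j <- which(bnd$id == bnd$mate_id[i])
    if (length(j) != 1) next
    j <- j[1]
    if (bnd$chrom[i] != bnd$chrom[j]) next
    ori_i <- if (grepl("\\[", bnd$alt[i])) "fwd" else "rev"
    ori_j <- if (grepl("\\[", bnd$alt[j])) "fwd" else "rev"
    if (ori_i != ori_j) next
    done <- c(done, bnd$id[i], bnd$id[j])
    out[[length(out) + 1]] <- tibble(
      chrom = bnd$chrom[i],
      pos = min(bnd$pos[i], bnd$pos[j]),
      sv_end = max(bnd$pos[i], bnd$pos[j]),
      var_class = "SV_INV",
      bnd_ids = paste(sort(c(bnd$id[i], bnd$id[j])), collapse = ",")
    )
  }
  if (length(out) == 0) {
    return(tibble(chrom = character(0), pos = numeric(0),
                  sv_end = numeric(0), var_class = character(0),
                  bnd_ids = character(0)))
  }
  list_rbind(out)
}
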