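# VCF emission and cohort-level simulation.

vcf_header <- function(layout, samples) {
  c("##fileformat=VCFv4.2",
    paste0("##contig=<ID=", names(layout), ",length=",
           format(layout, scientific = FALSE, trim = TRUE), ">"),
    "##FILTER=<ID=LowQual,Description=\"Failed caller sample or call filters\">",
    "##INFO=<ID=PAF,Number=1,Type=Float,Description=\"Population allele frequency\">",
    "##INFO=<ID=MAP,Number=1,Type=Integer,Description=\"1 if uniquely mappable\">",
    "##INFO=<ID=SVTYPE,Number=1,Type=String,Description=\"Structural variant type\">",
    "##INFO=<ID=END,Number=1,Type=Integer,Description=\"SV end position\">",
    "##INFO=<ID=INSLEN,Number=1,Type=Integer,Description=\"Resolved insertion length\">",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    "##FORMAT=<ID=AD,Number=R,Type=Integer,Description=\"Allele depths\">",
    "##FORMAT=<ID=DP,Number=1,Type=Integer,Description=\"Read depth\">",
    "##FORMAT=<ID=GQ,Number=1,Type=Integer,Description=\"Genotype quality\">",
    "##FORMAT=<ID=SR,Number=1,Type=Integer,Description=\"Alt-supporting split reads\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", samples), collapse = "\t"))
}

# records: tibble with chrom, pos, id, ref, alt, filter, info, is_sv,
# overrides (list of named character: clone -> sample field string)
build_vcf_body <- function(records, samples, depth) {
  small_default <- paste0("0/0:", depth, ",0:", depth, ":60")
  sv_default <- paste0(small_default, ":0")
  n <- nrow(records)
  k <- length(samples)
  fixed <- paste(records$chrom,
                 format(records$pos, scientific = FALSE, trim = TRUE),
                 records$id, records$ref, records$alt, ".", records$filter,
                 records$info,
                 ifelse(records$is_sv, "GT:AD:DP:GQ:SR", "GT:AD:DP:GQ"),
                 sep = "\t")
  mat <- matrix(ifelse(records$is_sv, sv_default, small_default), n, k)
  colnames(mat) <- samples
  ovs <- records$overrides
  for (i in seq_len(n)) {
    ov <- ovs[[i]]
    if (length(ov)) mat[i, names(ov)] <- ov
  }
  body <- do.call(paste, c(list(fixed), lapply(seq_len(k), function(j) {
    mat[, j]
  }), sep = "\t"))
  body
}

sample_field <- function(gt, alt_reads, depth, gq, sr = NULL) {
  ad <- paste0(depth - alt_reads, ",", alt_reads)
  base <- paste(gt, ad, depth, gq, sep = ":")
  if (is.null(sr)) base else paste(base, sr, sep = ":")
}

clone_gt <- function(ploidy) if (ploidy == "haploid") "1/1" else "0/1"

# VCF record rows (with per-clone overrides) from simulated variant records
records_to_vcf_rows <- function(rec, ploidy, depth) {
  is_sv <- startsWith(rec$var_class, "SV_")
  info <- rep("MAP=1", nrow(rec))
  info[is_sv] <- paste0(
    "MAP=1;SVTYPE=", sub("^SV_", "", rec$var_class[is_sv]), ";END=",
    format(rec$sv_end[is_sv], scientific = FALSE, trim = TRUE))
  has_len <- is_sv & !is.na(rec$ins_len)
  info[has_len] <- paste0(info[has_len], ";INSLEN=", rec$ins_len[has_len])
  base <- sample_field(clone_gt(ploidy), rec$alt_reads, depth,
                       rec$genotype_quality)
  ov_str <- ifelse(is_sv, paste(base, rec$split_reads, sep = ":"), base)
  tibble(chrom = rec$chrom, pos = rec$pos, id = ".", ref = rec$ref,
         alt = rec$alt, filter = "PASS", info = info, is_sv = is_sv,
         overrides = map2(ov_str, rec$clone_id, function(s, cl) {
           setNames(s, cl)
         }))
}

# records violating exactly one filter rule each, for filter testing
make_contaminants <- function(genome, used, clones, ploidy, depth) {
  if (nrow(clones) < 4) {
    abort("contaminant block needs >= 4 clones per cell line (cross-clone rules)")
  }
  pick_site <- function() {
    repeat {
      ch <- sample(names(genome), 1, prob = nchar(genome) / sum(nchar(genome)))
      p <- sample.int(nchar(genome[[ch]]) - 10L, 1) + 2L
      if (!is_used(used, ch, c(p, p + 1L))) {
        mark_used(used, ch, c(p, p + 1L))
        return(list(chrom = ch, pos = p,
                    ref = substr(genome[[ch]], p, p),
                    ref2 = substr(genome[[ch]], p, p + 1L)))
      }
    }
  }
  other_base <- function(b, n = 1) sample(setdiff(c("A", "C", "G", "T"), b), n)
  gt <- clone_gt(ploidy)
  c1 <- clones$clone_id[1]
  c2 <- clones$clone_id[2]
  ok <- function(alt_reads = 20, gq = 60) {
    sample_field(gt, alt_reads, depth, gq)
  }
  rows <- list()
  add <- function(rule, chrom, pos, ref, alt, filter = "PASS",
                  info = "MAP=1", ov) {
    rows[[length(rows) + 1]] <<- tibble(
      chrom = chrom, pos = pos, id = paste0("contam_", rule), ref = ref,
      alt = alt, filter = filter, info = info, is_sv = FALSE,
      overrides = list(ov), contam_rule = rule)
  }
  s <- pick_site()
  add("caller_fail", s$chrom, s$pos, s$ref, other_base(s$ref),
      filter = "LowQual", ov = setNames(ok(), c1))
  s <- pick_site()
  add("unmappable", s$chrom, s$pos, s$ref, other_base(s$ref),
      info = "MAP=0", ov = setNames(ok(), c1))
  s <- pick_site()
  add("pop_af", s$chrom, s$pos, s$ref, other_base(s$ref),
      info = "MAP=1;PAF=0.01", ov = setNames(ok(), c1))
  s <- pick_site()
  add("two_clones", s$chrom, s$pos, s$ref, other_base(s$ref),
      ov = setNames(c(ok(), ok()), c(c1, c2)))
  s <- pick_site()
  ab <- other_base(s$ref, 2)
  add("multiallelic", s$chrom, s$pos, s$ref, paste(ab, collapse = ","),
      ov = setNames(paste0("1/2:", depth - 20, ",10,10:", depth, ":60"), c1))
  s <- pick_site()
  add("one_read", s$chrom, s$pos, s$ref, other_base(s$ref),
      ov = setNames(ok(alt_reads = 1), c1))
  # indel-specific rules
  s <- pick_site()
  add("indel_low_gq", s$chrom, s$pos, s$ref2, substr(s$ref2, 1, 1),
      ov = setNames(ok(gq = 9), c1))
  s <- pick_site()
  others3 <- clones$clone_id[2:4]
  add("indel_other_any", s$chrom, s$pos, s$ref2, substr(s$ref2, 1, 1),
      ov = setNames(c(ok(), sample_field("0/0", 1, depth, 60),
                      sample_field("0/0", 1, depth, 60),
                      sample_field("0/0", 1, depth, 60)),
                    c(c1, others3)))
  s <- pick_site()
  add("indel_other_two", s$chrom, s$pos, s$ref2, substr(s$ref2, 1, 1),
      ov = setNames(c(ok(), sample_field("0/0", 2, depth, 60),
                      sample_field("0/0", 2, depth, 60)),
                    c(c1, c2, clones$clone_id[3])))
  # SV-specific rule
  s <- pick_site()
  rows[[length(rows) + 1]] <- tibble(
    chrom = s$chrom, pos = s$pos, id = "contam_sv_one_split", ref = s$ref,
    alt = "<DEL>", filter = "PASS",
    info = paste0("MAP=1;SVTYPE=DEL;END=", s$pos + 5000L), is_sv = TRUE,
    overrides = list(setNames(
      sample_field(gt, 15, depth, 60, sr = 1), c1)),
    contam_rule = "sv_one_split")
  list_rbind(rows)
}

#' Simulate a full multi-cell-line clone cohort with known truth
#'
#' Generates a toy genome, simulates every clone of the design, and writes
#' one jointly genotyped multi-sample VCF per cell line (each variant
#' genotyped only in its own clone, so the single-clone filter rule holds
#' by construction), together with the genome FASTA, a design TSV and a
#' truth TSV. Optionally appends contaminant records that violate each
#' filter rule exactly once, so filter cascades can be validated
#' record-for-record. Deterministic given `seed`.
#'
#' @param design Design list from [default_design()] (or a modified copy).
#' @param out_dir Output directory (created if needed).
#' @param seed Integer master seed.
#' @param contaminants Include the per-rule contaminant block.
#' @return Object of class `radmut_simulation`: list with `design`,
#'   `genome`, file paths (`genome_path`, `vcf_paths`, `design_path`,
#'   `truth_path`), the `truth` tibble (one row per emitted non-contaminant
#'   record) and `contaminants`.
#' @export
simulate_cohort <- function(design = default_design(), out_dir,
                            seed = NULL, contaminants = TRUE) {
  clones <- design$clones
  if (anyDuplicated(clones$clone_id)) abort("duplicate clone ids in design")
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  seeds <- withr::with_seed(seed, {
    sample.int(2^31 - 2, nrow(clones) + 1 + length(unique(clones$cell_line)))
  })
  genome <- make_toy_genome(design$layout, design$gc_fraction,
                           seed = seeds[1])
  genome_path <- file.path(out_dir, "genome.fa")
  write_genome(genome, genome_path)

  used <- new_used_sites()
  run_cache <- new.env(parent = emptyenv())
  truth <- list()
  vcf_paths <- c()
  contam_all <- list()
  lines_of <- split(seq_len(nrow(clones)), clones$cell_line)
  li <- 0L
  for (cl_line in unique(clones$cell_line)) {
    li <- li + 1L
    idx <- lines_of[[cl_line]]
    line_clones <- clones[idx, ]
    ploidy <- line_clones$ploidy[1]
    samples <- line_clones$clone_id
    rec_rows <- list()
    for (j in idx) {
      rec <- simulate_clone(genome, clones[j, ], depth = design$depth,
                            used = used, seed = seeds[1 + j],
                            run_cache = run_cache)
      truth[[length(truth) + 1]] <- rec
      rec_rows[[length(rec_rows) + 1]] <-
        records_to_vcf_rows(rec, ploidy, design$depth)
    }
    records <- list_rbind(rec_rows)
    if (contaminants) {
      contam <- withr::with_seed(seeds[nrow(clones) + 1 + li] %% (2^31 - 2), {
        make_contaminants(genome, used, line_clones, ploidy, design$depth)
      })
      contam_all[[cl_line]] <- mutate(contam, cell_line = cl_line)
      records <- bind_rows(records, select(contam, -"contam_rule"))
    }
    records <- arrange(records, match(.data$chrom, names(genome)), .data$pos)
    path <- file.path(out_dir, paste0(cl_line, ".vcf"))
    writeLines(c(vcf_header(design$layout, samples),
                 build_vcf_body(records, samples, design$depth)), path)
    vcf_paths[cl_line] <- path
  }

  truth <- list_rbind(truth)
  truth_path <- file.path(out_dir, "truth.tsv")
  readr::write_tsv(truth, truth_path)
  design_path <- file.path(out_dir, "design.tsv")
  readr::write_tsv(
    select(clones, "clone_id", "cell_line", "treatment", "ploidy",
           "n_snv", "n_del", "n_ins"),
    design_path)

  structure(
    list(design = design, genome = genome, genome_path = genome_path,
         vcf_paths = vcf_paths, design_path = design_path,
         truth_path = truth_path, truth = truth,
         contaminants = if (contaminants) list_rbind(contam_all) else NULL),
    class = "radmut_simulation")
}

#' @export
print.radmut_simulation <- function(x, ...) {
  cat("Simulated clone cohort\n")
  cat("  cell lines:", length(x$vcf_paths), " clones:",
      nrow(x$design$clones), "\n")
  cat("  emitted records:", nrow(x$truth), "(+",
      if (is.null(x$contaminants)) 0 else nrow(x$contaminants),
      "contaminants)\n")
  cat("  files under:", dirname(x$genome_path), "\n")
  invisible(x)
}

#' Read a simulated cohort's VCFs back as clone cohorts
#'
#' @param sim A `radmut_simulation`.
#' @return Named list of `clone_cohort` objects, one per cell line.
#' @export
read_simulated_cohorts <- function(sim) {
  clones <- sim$design$clones
  out <- list()
  for (cl_line in names(sim$vcf_paths)) {
    cc <- clones[clones$cell_line == cl_line, ]
    out[[cl_line]] <- read_cohort_vcf(
      sim$vcf_paths[[cl_line]],
      setNames(cc$treatment, cc$clone_id),
      cell_line = cl_line)
  }
  out
}

#' Simulate a multinomial signature count catalog
#'
#' Draws per-clone category counts from exposure-weighted mixtures of the
#' given spectra — the direct (genome-free) route to a count matrix for
#' testing signature extraction.
#'
#' @param spectra Categories x signatures matrix (columns sum to 1).
#' @param n_clones Number of clones.
#' @param burden_range Per-clone total mutation counts are drawn uniformly
#'   from this range.
#' @param exposures Optional signatures x clones matrix of exposure
#'   fractions (columns sum to 1); random if omitted.
#' @param seed Integer seed.
#' @return List with `catalog` (count-matrix tibble), `exposure_fractions`
#'   and `exposure_counts` (signatures x clones).
#' @export
simulate_signature_catalog <- function(spectra, n_clones = 21,
                                       burden_range = c(2000, 5000),
                                       exposures = NULL, seed = NULL) {
  withr::with_seed(seed, {
    k <- ncol(spectra)
    if (is.null(exposures)) {
      raw <- matrix(stats::rexp(k * n_clones), k, n_clones)
      exposures <- sweep(raw, 2, colSums(raw), "/")
    }
    burdens <- sample(seq(burden_range[1], burden_range[2]), n_clones,
                      replace = TRUE)
    counts <- vapply(seq_len(n_clones), function(j) {
      mix <- as.numeric(spectra %*% exposures[, j])
      as.numeric(rmultinom(1, burdens[j], mix))
    }, numeric(nrow(spectra)))
    clone_ids <- sprintf("sim%02d", seq_len(n_clones))
    colnames(counts) <- clone_ids
    rownames(counts) <- rownames(spectra)
    colnames(exposures) <- clone_ids
    rownames(exposures) <- colnames(spectra)
    catalog <- as_tibble(counts, rownames = "category")
    list(catalog = catalog,
         exposure_fractions = exposures,
         exposure_counts = sweep(exposures, 2, burdens, "*"))
  })
}
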