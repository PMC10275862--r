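#' Filter cascades for clone-private somatic variants
#'
#' The six shared rules retain a record only when (1) it passed both the
#' caller's sample and call filters, (2) it lies in uniquely mappable
#' sequence, (3) its population allele frequency is missing (absent from
#' the database) or below `af_max`, (4) it is genotyped in exactly one
#' clone of the cohort, (5) the VCF row is not multiallelic, and (6) the
#' genotyped clone has at least two alt-supporting reads. Small indels must
#' additionally have genotype quality >= `gq_min` in the genotyped clone,
#' at most two other clones with any alt-supporting read, and at most one
#' other clone with two or more such reads (rules against germline leakage
#' genotyped in one clone only). Structural variants replace rule (6) by
#' requiring at least `sr_min` alt-supporting split reads in the genotyped
#' clone, with no spanning-read requirement. Each retained record is
#' attributed to its single genotyped clone and carries its VAF there.
#'
#' Rules can be toggled off via `rules` for diagnostics; removing a rule
#' always yields a superset of the all-rules output.
#'
#' @param cohort A `clone_cohort` from [read_cohort_vcf()].
#' @param af_max Population allele-frequency ceiling (strict `<`; the
#'   published cascade uses 0.1%).
#' @param rules Subset of the rule names to apply (defaults to all):
#'   `caller_pass`, `mappable`, `pop_af`, `single_clone`, `multiallelic`,
#'   `min_alt_reads` plus, for indels, `genotype_quality`,
#'   `other_clones_any`, `other_clones_two`, and for SVs `split_reads`.
#' @return The cohort restricted to retained records of the relevant
#'   class, with `clone_id` (attributed clone) and `vaf` columns added to
#'   `variants`.
#' @name filter_cascades
NULL

snv_rule_names <- function() {
  c("caller_pass", "mappable", "pop_af", "single_clone", "multiallelic",
    "min_alt_reads")
}

# columns added by a previous filter pass; dropped so filtering is idempotent
attribution_cols <- function() {
  c("clone_id", "vaf", "n_genotyped", "own_alt_reads", "own_depth",
    "own_gq", "own_split_reads", "n_other_any", "n_other_two")
}

# per-variant attribution summary from the evidence table
attribution_summary <- function(cohort) {
  geno <- cohort$evidence |>
    group_by(.data$variant_id) |>
    summarise(
      n_genotyped = sum(.data$genotyped, na.rm = TRUE),
      clone_id = if (sum(.data$genotyped, na.rm = TRUE) == 1) {
        .data$clone_id[which(.data$genotyped)]
      } else {
        NA_character_
      },
      .groups = "drop"
    )
  own <- cohort$evidence |>
    inner_join(select(geno, "variant_id", "clone_id"),
               by = c("variant_id", "clone_id")) |>
    select("variant_id",
           own_alt_reads = "alt_reads", own_depth = "depth",
           own_gq = "genotype_quality", own_split_reads = "split_reads")
  others <- cohort$evidence |>
    left_join(select(geno, "variant_id", attributed = "clone_id"),
              by = "variant_id") |>
    filter(is.na(.data$attributed) | .data$clone_id != .data$attributed) |>
    group_by(.data$variant_id) |>
    summarise(
      n_other_any = sum(.data$alt_reads >= 1, na.rm = TRUE),
      n_other_two = sum(.data$alt_reads >= 2, na.rm = TRUE),
      .groups = "drop"
    )
  geno |>
    left_join(own, by = "variant_id") |>
    left_join(others, by = "variant_id")
}

apply_shared_rules <- function(v, rules, af_max) {
  keep <- rep(TRUE, nrow(v))
  if ("caller_pass" %in% rules) keep <- keep & v$caller_pass
  if ("mappable" %in% rules) keep <- keep & !is.na(v$mappable) & v$mappable
  if ("pop_af" %in% rules) keep <- keep & (is.na(v$pop_af) | v$pop_af < af_max)
  if ("single_clone" %in% rules) keep <- keep & v$n_genotyped == 1
  if ("multiallelic" %in% rules) keep <- keep & !v$multiallelic
  keep
}

finish_filter <- function(cohort, v, keep, label) {
  v <- v[keep, , drop = FALSE] |>
    mutate(vaf = ifelse(.data$own_depth > 0,
                        .data$own_alt_reads / .data$own_depth, NA_real_)) |>
    select(-"n_genotyped", -"n_other_any", -"n_other_two")
  out <- new_clone_cohort(
    cohort$cell_line, cohort$clones,
    v,
    semi_join(cohort$evidence, v, by = "variant_id")
  )
  attr(out, "filtered") <- label
  out
}

#' @rdname filter_cascades
#' @export
filter_snvs <- function(cohort, af_max = 0.001, rules = snv_rule_names()) {
  stopifnot(inherits(cohort, "clone_cohort"))
  v <- cohort$variants |>
    filter(.data$var_class == "SNV") |>
    select(-any_of(attribution_cols())) |>
    left_join(attribution_summary(cohort), by = "variant_id")
  keep <- apply_shared_rules(v, rules, af_max)
  if ("min_alt_reads" %in% rules) {
    keep <- keep & !is.na(v$own_alt_reads) & v$own_alt_reads >= 2
  }
  keep[is.na(keep)] <- FALSE
  finish_filter(cohort, v, keep, "SNV")
}

#' @rdname filter_cascades
#' @param gq_min Minimum genotype quality in the attributed clone (indels).
#' @export
filter_indels <- function(cohort, af_max = 0.001, gq_min = 10,
                          rules = c(snv_rule_names(), "genotype_quality",
                                    "other_clones_any", "other_clones_two")) {
  stopifnot(inherits(cohort, "clone_cohort"))
  v <- cohort$variants |>
    filter(.data$var_class %in% c("INS", "DEL")) |>
    select(-any_of(attribution_cols())) |>
    left_join(attribution_summary(cohort), by = "variant_id")
  keep <- apply_shared_rules(v, rules, af_max)
  if ("min_alt_reads" %in% rules) {
    keep <- keep & !is.na(v$own_alt_reads) & v$own_alt_reads >= 2
  }
  if ("genotype_quality" %in% rules) {
    keep <- keep & !is.na(v$own_gq) & v$own_gq >= gq_min
  }
  if ("other_clones_any" %in% rules) keep <- keep & v$n_other_any <= 2
  if ("other_clones_two" %in% rules) keep <- keep & v$n_other_two <= 1
  keep[is.na(keep)] <- FALSE
  finish_filter(cohort, v, keep, "indel")
}

#' @rdname filter_cascades
#' @param sr_min Minimum alt-supporting split reads in the attributed clone.
#' @export
filter_svs <- function(cohort, af_max = 0.001, sr_min = 2,
                       rules = c(setdiff(snv_rule_names(), "min_alt_reads"),
                                 "split_reads")) {
  stopifnot(inherits(cohort, "clone_cohort"))
  v <- cohort$variants |>
    filter(startsWith(.data$var_class, "SV_")) |>
    select(-any_of(attribution_cols())) |>
    left_join(attribution_summary(cohort), by = "variant_id")
  keep <- apply_shared_rules(v, rules, af_max)
  if ("split_reads" %in% rules) {
    keep <- keep & !is.na(v$own_split_reads) & v$own_split_reads >= sr_min
  }
  keep[is.na(keep)] <- FALSE
  finish_filter(cohort, v, keep, "SV")
}

#' Attributed variants of a filtered cohort as a tibble
#'
#' @param cohort A filtered `clone_cohort`.
#' @return Tibble with `chrom`, `pos`, `ref`, `alt`, `var_class`,
#'   `clone_id`, `vaf` (plus `sv_end` for SVs), suitable for the
#'   classification and clustering stages.
#' @export
attributed_variants <- function(cohort) {
  stopifnot(inherits(cohort, "clone_cohort"))
  if (!"clone_id" %in% names(cohort$variants)) {
    abort("cohort is unfiltered; run filter_snvs()/filter_indels()/filter_svs()")
  }
  cohort$variants |>
    select("chrom", "pos", "ref", "alt", "var_class", "clone_id", "vaf",
           any_of("sv_end")) |>
    left_join(cohort$clones, by = "clone_id")
}

#' Write the per-clone attributed variant table as TSV
#'
#' @param cohort A filtered `clone_cohort`.
#' @param path Output TSV path.
#' @export
write_variants_tsv <- function(cohort, path) {
  readr::write_tsv(attributed_variants(cohort), path)
  invisible(path)
}
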