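#' Empirical p-value from exceedance counts
#'
#' The add-one empirical p-value p = (r + 1) / (n + 1), where `r` is the
#' number of randomized statistics at least as extreme as the observed one
#' over `n` randomizations. Never returns 0; the minimum attainable value is
#' 1 / (n + 1).
#'
#' @param r Exceedance count(s), `0 <= r <= n`.
#' @param n Number of randomization iterations.
#' @return Numeric vector of p-values in (0, 1].
#' @export
#' @examples
#' empirical_p(4, 99) # 0.05
empirical_p <- function(r, n) {
  if (any(n < 1)) abort("`n` must be >= 1")
  if (any(r < 0 | r > n)) abort("`r` must lie in [0, n]")
  (r + 1) / (n + 1)
}

# all comparisons the cohort supports: treatment pairs within each cell line
# and pooled, plus cell-line pairs within each treatment and pooled
default_comparisons <- function(clones) {
  trt <- sort(unique(clones$treatment))
  cl <- sort(unique(clones$cell_line))
  out <- list()
  if (length(trt) > 1) {
    pairs <- utils::combn(trt, 2, simplify = FALSE)
    for (p in pairs) {
      out[[length(out) + 1]] <- tibble(
        group_by_col = "treatment", group_a = p[1], group_b = p[2],
        stratum_col = NA_character_, stratum = "pooled")
      for (s in cl) {
        out[[length(out) + 1]] <- tibble(
          group_by_col = "treatment", group_a = p[1], group_b = p[2],
          stratum_col = "cell_line", stratum = s)
      }
    }
  }
  if (length(cl) > 1) {
    pairs <- utils::combn(cl, 2, simplify = FALSE)
    for (p in pairs) {
      out[[length(out) + 1]] <- tibble(
        group_by_col = "cell_line", group_a = p[1], group_b = p[2],
        stratum_col = NA_character_, stratum = "pooled")
      for (s in trt) {
        out[[length(out) + 1]] <- tibble(
          group_by_col = "cell_line", group_a = p[1], group_b = p[2],
          stratum_col = "treatment", stratum = s)
      }
    }
  }
  list_rbind(out)
}

#' Label-shuffling randomization test for group differences in clone
#' statistics
#'
#' For every requested statistic and pairwise group comparison, the observed
#' difference in group means is compared against the null distribution
#' obtained by shuffling the clone labels globally across the whole cohort
#' (equivalently, permuting the per-clone values while the design stays
#' fixed) `n_iter` times. Group means are recomputed after each shuffle,
#' also for comparisons stratified by cell line or treatment. Two empirical
#' p-values are reported per comparison — the fractions of shuffles with a
#' difference `>=` resp. `<=` the observed one, each computed as
#' (r + 1)/(n + 1) — together with their minimum as the headline `p`.
#'
#' @param stats Data frame with one row per clone and statistic: columns
#'   `clone_id`, `cell_line`, `treatment`, `statistic`, `value`.
#' @param comparisons Optional tibble of comparisons (columns
#'   `group_by_col`, `group_a`, `group_b`, `stratum_col`, `stratum`); by
#'   default all treatment and cell-line pairs, pooled and stratified.
#' @param n_iter Number of label shuffles.
#' @param seed Integer seed; shuffles are shared across statistics and
#'   comparisons, making results deterministic given the seed.
#' @return Tibble of class `radmut_permtest` with the observed difference
#'   (`mean(group_a) - mean(group_b)`), exceedance counts `r_ge`/`r_le`,
#'   empirical `p_ge`/`p_le` and `p = min(p_ge, p_le)`.
#' @export
permutation_test <- function(stats, comparisons = NULL, n_iter = 100000,
                             seed = NULL) {
  stats <- as_tibble(stats)
  need <- c("clone_id", "cell_line", "treatment", "statistic", "value")
  stopifnot(all(need %in% names(stats)))
  clones <- distinct(stats, .data$clone_id, .data$cell_line, .data$treatment)
  if (anyDuplicated(clones$clone_id)) {
    abort("a clone_id maps to more than one cell_line/treatment")
  }
  n_clones <- nrow(clones)
  if (is.null(comparisons)) comparisons <- default_comparisons(clones)

  perm <- withr::with_seed(seed, {
    matrix(unlist(lapply(seq_len(n_iter),
                         function(i) sample.int(n_clones))),
           nrow = n_iter, byrow = TRUE)
  })

  results <- list()
  for (st in unique(stats$statistic)) {
    v <- stats |>
      filter(.data$statistic == st) |>
      select("clone_id", "value")
    v <- v$value[match(clones$clone_id, v$clone_id)]
    if (anyNA(v)) abort(paste0("statistic `", st, "` missing for some clones"))
    vperm <- matrix(v[perm], nrow = n_iter)
    for (i in seq_len(nrow(comparisons))) {
      cmp <- comparisons[i, ]
      grp <- clones[[cmp$group_by_col]]
      in_stratum <- if (is.na(cmp$stratum_col)) {
        rep(TRUE, n_clones)
      } else {
        clones[[cmp$stratum_col]] == cmp$stratum
      }
      ia <- which(grp == cmp$group_a & in_stratum)
      ib <- which(grp == cmp$group_b & in_stratum)
      if (length(ia) == 0 || length(ib) == 0) {
        abort(paste0("empty group in comparison ", cmp$group_a, " vs ",
                     cmp$group_b, " (", cmp$stratum, ")"))
      }
      w <- numeric(n_clones)
      w[ia] <- 1 / length(ia)
      w[ib] <- w[ib] - 1 / length(ib)
      obs <- sum(v * w)
      diffs <- as.numeric(vperm %*% w)
      # tolerance so ties at the observed value count as exceedances on
      # both sides despite floating-point summation-order noise
      tol <- 1e-8 * (1 + abs(obs) + max(abs(v)))
      r_ge <- sum(diffs >= obs - tol)
      r_le <- sum(diffs <= obs + tol)
      results[[length(results) + 1]] <- tibble(
        statistic = st,
        comparison = cmp$group_by_col,
        group_a = cmp$group_a, group_b = cmp$group_b,
        stratum = cmp$stratum,
        n_a = length(ia), n_b = length(ib),
        observed_diff = obs, n_iter = n_iter,
        r_ge = r_ge, r_le = r_le,
        p_ge = empirical_p(r_ge, n_iter),
        p_le = empirical_p(r_le, n_iter)
      )
    }
  }
  out <- list_rbind(results) |>
    mutate(p = pmin(.data$p_ge, .data$p_le))
  class(out) <- c("radmut_permtest", class(out))
  out
}

#' Benjamini-Hochberg correction within statistic families
#'
#' Adjusts the headline empirical p-values for multiple testing separately
#' within each family (e.g. SNV signatures, indel signatures, burdens), as
#' step-up FDR q-values. Comparisons with an unadjusted p of at most
#' `flag_at` are flagged for reporting.
#'
#' @param results A `radmut_permtest` tibble (or any tibble with a `p`
#'   column).
#' @param family Either a column name in `results` or a vector assigning
#'   each row to a family; `NULL` treats all rows as one family.
#' @param flag_at Unadjusted-p reporting threshold.
#' @return `results` with added columns `q` and `reported`.
#' @export
fdr_adjust <- function(results, family = NULL, flag_at = 0.1) {
  results <- as_tibble(results)
  fam <- if (is.null(family)) {
    rep("all", nrow(results))
  } else if (length(family) == 1 && family %in% names(results)) {
    results[[family]]
  } else {
    family
  }
  q <- numeric(nrow(results))
  for (f in unique(fam)) {
    idx <- which(fam == f)
    q[idx] <- p.adjust(results$p[idx], method = "BH")
  }
  mutate(results, q = q, reported = .data$p <= flag_at)
}

#' Deletion-to-insertion burden ratio
#'
#' For small indels, the ratio of deletion to insertion counts; for
#' structural variants, deletions over insertions plus tandem duplications,
#' log2-transformed.
#'
#' @param deletions,insertions Non-negative counts (vectors allowed). In SV
#'   mode `insertions` should already include duplications.
#' @param mode `"small-indel"` or `"sv"`.
#' @param pseudocount Added to both counts when positive; with the default 0
#'   a zero denominator yields `NA` (excluded from pooling).
#' @return Tibble with the counts, `ratio` and (SV mode) `log2_ratio`.
#' @export
del_ins_ratio <- function(deletions, insertions, mode = c("small-indel", "sv"),
                          pseudocount = 0) {
  mode <- match.arg(mode)
  if (any(deletions < 0 | insertions < 0)) abort("counts must be >= 0")
  num <- deletions + pseudocount
  den <- insertions + pseudocount
  ratio <- ifelse(den > 0, num / den, NA_real_)
  out <- tibble(deletions = deletions, insertions = insertions,
                mode = mode, ratio = ratio)
  if (mode == "sv") out$log2_ratio <- log2(out$ratio)
  out
}

#' Two-sample t comparison of lengths or distances
#'
#' Welch two-sample t-test on (optionally log-transformed) values, as used
#' for inter-mutation distances and SV length comparisons. Degenerate input
#' with zero variance in both groups and equal means returns t = 0, p = 1.
#'
#' @param a,b Numeric vectors with at least two values each.
#' @param log10_transform Compare on the log10 scale.
#' @return Tibble with `t`, `df`, `p`, `mean_a`, `mean_b`.
#' @export
compare_lengths <- function(a, b, log10_transform = FALSE) {
  if (length(a) < 2 || length(b) < 2) abort("each group needs >= 2 values")
  if (log10_transform) {
    a <- log10(a)
    b <- log10(b)
  }
  if (sd(a) == 0 && sd(b) == 0) {
    if (mean(a) == mean(b)) {
      return(tibble(t = 0, df = NA_real_, p = 1,
                    mean_a = mean(a), mean_b = mean(b)))
    }
    abort("zero within-group variance with unequal means: t undefined")
  }
  tt <- t.test(a, b)
  tibble(t = unname(tt$statistic), df = unname(tt$parameter),
         p = tt$p.value, mean_a = mean(a), mean_b = mean(b))
}
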