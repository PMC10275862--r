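#' Convert between VCF 1-based and BED 0-based half-open coordinates
#'
#' All coordinate conversion in the package goes through these helpers:
#' a 1-based position `p` corresponds to the 0-based half-open interval
#' `[p - 1, p)`.
#'
#' @param pos 1-based positions.
#' @return 0-based positions (or vice versa).
#' @export
pos_to_bed <- function(pos) pos - 1L

#' @rdname pos_to_bed
#' @param bed_pos 0-based positions.
#' @export
bed_to_pos <- function(bed_pos) bed_pos + 1L

#' Read a BED file of genomic bins with covariate columns
#'
#' @param path BED path (0-based half-open). Columns beyond chrom/start/end
#'   are read as covariates; the 4th column is named `covariate_level`
#'   unless a header supplies names.
#' @return Tibble with `chrom`, `start`, `end` and any covariate columns.
#' @export
read_bins_bed <- function(path) {
  first <- readr::read_lines(path, n_max = 1)
  has_header <- grepl("^(#|track|browser)|chrom", first)
  out <- readr::read_tsv(path, col_names = has_header,
                         comment = "#", show_col_types = FALSE)
  if (!has_header) {
    base <- c("chrom", "start", "end", "covariate_level")
    names(out)[seq_len(min(4, ncol(out)))] <- base[seq_len(min(4, ncol(out)))]
  } else {
    names(out)[1:3] <- c("chrom", "start", "end")
  }
  out
}

#' Count mutations per genomic bin
#'
#' Assigns each mutation (1-based position) to the 0-based half-open bin
#' containing it. Bins must be non-overlapping within the track. Mutations
#' falling outside all bins are tallied in the `unassigned` attribute, so
#' total mutations = sum of bin counts + unassigned.
#'
#' @param mutations Data frame with `chrom` and `pos` (1-based).
#' @param bins Data frame with `chrom`, `start`, `end` (0-based half-open)
#'   plus covariate columns.
#' @return `bins` with an added `mutation_count` column and attribute
#'   `unassigned`.
#' @export
count_mutations_per_bin <- function(mutations, bins) {
  mutations <- as_tibble(mutations)
  bins <- as_tibble(bins) |>
    mutate(.bin_id = dplyr::row_number())
  if (any(bins$end <= bins$start)) abort("bins must satisfy end > start")
  ovl <- bins |>
    group_by(.data$chrom) |>
    arrange(.data$start, .by_group = TRUE) |>
    filter(dplyr::lag(.data$end, default = -Inf) > .data$start) |>
    ungroup()
  if (nrow(ovl) > 0) abort("overlapping bins within the track")

  assigned <- integer(0)
  if (nrow(mutations) > 0) {
    p0 <- pos_to_bed(mutations$pos)
    assigned <- rep(NA_integer_, nrow(mutations))
    for (ch in unique(mutations$chrom)) {
      b <- bins |> filter(.data$chrom == ch) |> arrange(.data$start)
      mi <- which(mutations$chrom == ch)
      if (nrow(b) == 0) next
      idx <- findInterval(p0[mi], b$start)
      ok <- idx >= 1 & p0[mi] < b$end[pmax(idx, 1)]
      assigned[mi[ok]] <- b$.bin_id[idx[ok]]
    }
  }
  counts <- table(factor(assigned, levels = bins$.bin_id))
  out <- bins |>
    mutate(mutation_count = as.integer(counts)) |>
    select(-".bin_id")
  attr(out, "unassigned") <- sum(is.na(assigned))
  out
}

#' Negative binomial regression of per-bin mutation counts
#'
#' Fits a negative binomial generalized linear model (log link, maximum
#' likelihood dispersion via `MASS::glm.nb`) of mutation counts on an
#' ordinal covariate level (e.g. replication-timing quantile or expression
#' level). Sequence composition is controlled either through a
#' log-opportunity offset computed from the per-bin at-risk site counts
#' (default) or by entering log-opportunity as a covariate term.
#' Covariate-level coefficients are log rate ratios relative to the
#' reference level.
#'
#' @param bins Tibble with `mutation_count`, a `covariate_level` column and
#'   (unless `opportunity_col` is NULL) an opportunity column of at-risk
#'   site counts.
#' @param level_col Name of the covariate-level column.
#' @param opportunity_col Name of the opportunity column, or `NULL` for no
#'   composition control.
#' @param context_mode `"offset"` or `"covariate"`.
#' @param extra_terms Character vector of additional covariate column names
#'   (e.g. mutation type).
#' @return Object of class `radmut_nbfit` wrapping the `glm.nb` fit, with
#'   [generics::tidy()] and [generics::glance()] methods.
#' @export
fit_nb_regression <- function(bins, level_col = "covariate_level",
                              opportunity_col = "opportunity",
                              context_mode = c("offset", "covariate"),
                              extra_terms = NULL) {
  context_mode <- match.arg(context_mode)
  bins <- as_tibble(bins)
  if (!"mutation_count" %in% names(bins)) {
    abort("`bins` must carry a mutation_count column; see count_mutations_per_bin()")
  }
  if (length(unique(bins[[level_col]])) < 2) {
    abort("need >= 2 covariate levels")
  }
  df <- tibble(
    count = bins$mutation_count,
    level = factor(bins[[level_col]])
  )
  for (tm in extra_terms) df[[tm]] <- bins[[tm]]
  rhs <- paste(c("level", extra_terms), collapse = " + ")
  if (!is.null(opportunity_col)) {
    opp <- bins[[opportunity_col]]
    if (any(opp <= 0)) abort("opportunity must be positive")
    df$log_opportunity <- log(opp)
    rhs <- if (context_mode == "offset") {
      paste0(rhs, " + offset(log_opportunity)")
    } else {
      paste0(rhs, " + log_opportunity")
    }
  }
  form <- stats::as.formula(paste("count ~", rhs))
  fit <- tryCatch(
    suppressWarnings(MASS::glm.nb(form, data = df)),
    error = function(e) {
      abort(paste0("negative binomial fit failed (degenerate design?): ",
                   conditionMessage(e)))
    }
  )
  structure(list(fit = fit, context_mode = context_mode,
                 levels = levels(df$level)),
            class = "radmut_nbfit")
}

#' @export
print.radmut_nbfit <- function(x, ...) {
  cat("Negative binomial mutation-rate regression\n")
  cat("  dispersion (theta):", sprintf("%.3f", x$fit$theta), "\n")
  print(tidy.radmut_nbfit(x))
  invisible(x)
}

#' @export
tidy.radmut_nbfit <- function(x, ...) {
  s <- summary(x$fit)$coefficients
  tibble(term = rownames(s), estimate = s[, 1], std_error = s[, 2],
         statistic = s[, 3], p_value = s[, 4])
}

#' @export
glance.radmut_nbfit <- function(x, ...) {
  tibble(theta = x$fit$theta, aic = x$fit$aic,
         deviance = x$fit$deviance, df_residual = x$fit$df.residual,
         converged = x$fit$converged)
}

#' Test whether treatment changes the regional mutation-rate relationship
#'
#' Fits a joint negative binomial model with a treatment-by-covariate-level
#' interaction on per-bin counts observed per treatment group, and reports
#' Wald p-values for the interaction terms. A non-significant interaction
#' means the association of mutation density with the regional covariate
#' (e.g. replication timing) does not differ between treatments.
#'
#' @param bins Tibble with `mutation_count`, covariate level, a `treatment`
#'   column and (optionally) opportunity, one row per bin x treatment.
#' @inheritParams fit_nb_regression
#' @param treatment_col Name of the treatment column.
#' @return List with `fit` (a `radmut_nbfit`) and `interaction`, a tibble
#'   of interaction coefficients with Wald p-values.
#' @export
compare_treatment_slopes <- function(bins, level_col = "covariate_level",
                                     treatment_col = "treatment",
                                     opportunity_col = "opportunity",
                                     context_mode = c("offset", "covariate")) {
  context_mode <- match.arg(context_mode)
  bins <- as_tibble(bins)
  if (length(unique(bins[[treatment_col]])) < 2) {
    abort("interaction undefined with a single treatment group")
  }
  df <- tibble(
    count = bins$mutation_count,
    level = factor(bins[[level_col]]),
    treatment = factor(bins[[treatment_col]])
  )
  rhs <- "level * treatment"
  if (!is.null(opportunity_col) && opportunity_col %in% names(bins)) {
    df$log_opportunity <- log(bins[[opportunity_col]])
    rhs <- if (context_mode == "offset") {
      paste0(rhs, " + offset(log_opportunity)")
    } else {
      paste0(rhs, " + log_opportunity")
    }
  }
  form <- stats::as.formula(paste("count ~", rhs))
  fit <- tryCatch(
    suppressWarnings(MASS::glm.nb(form, data = df)),
    error = function(e) {
      abort(paste0("negative binomial fit failed (degenerate design?): ",
                   conditionMessage(e)))
    }
  )
  wrapped <- structure(list(fit = fit, context_mode = context_mode,
                            levels = levels(df$level)),
                       class = "radmut_nbfit")
  coefs <- tidy.radmut_nbfit(wrapped)
  interaction <- filter(coefs, grepl(":", .data$term))
  list(fit = wrapped, interaction = interaction)
}

#' Simulate genomic bins with a covariate-dependent mutation rate
#'
#' Generates per-bin mutation counts from a negative binomial model with a
#' log-linear covariate-level effect and a lognormal opportunity, for
#' testing the regional regression: counts ~ NB(mu, theta) with
#' mu = opportunity * base_rate * rate_ratio^(level - 1).
#'
#' @param n_bins Number of bins.
#' @param n_levels Number of ordinal covariate levels (bins split evenly).
#' @param rate_ratio Multiplicative rate change per level step (2 means the
#'   last level has twice the rate of the first when `n_levels = 2`).
#' @param base_rate Mutations per opportunity unit at level 1.
#' @param theta NB dispersion (larger = closer to Poisson).
#' @param mean_opportunity Mean opportunity per bin.
#' @param treatments Optional character vector; when given, each bin is
#'   replicated per treatment with `treatment_ratios` scaling the level
#'   effect.
#' @param treatment_ratios Per-treatment multiplier applied to the
#'   per-level log slope (1 = same slope).
#' @param seed Integer seed.
#' @return Tibble with `chrom`, `start`, `end`, `covariate_level`,
#'   `opportunity`, `mutation_count` (and `treatment` if requested).
#' @export
simulate_regional_bins <- function(n_bins = 2000, n_levels = 2,
                                   rate_ratio = 2, base_rate = 2e-3,
                                   theta = 5, mean_opportunity = 2000,
                                   treatments = NULL,
                                   treatment_ratios = NULL, seed = NULL) {
  withr::with_seed(seed, {
    level <- rep(seq_len(n_levels), length.out = n_bins)
    width <- 10000L
    bins <- tibble(
      chrom = "chr1",
      start = (seq_len(n_bins) - 1L) * width,
      end = seq_len(n_bins) * width,
      covariate_level = level,
      opportunity = rlnorm(n_bins, log(mean_opportunity), 0.2)
    )
    slope <- log(rate_ratio)
    if (is.null(treatments)) {
      mu <- bins$opportunity * base_rate * exp(slope * (level - 1))
      bins$mutation_count <- rnbinom(n_bins, size = theta, mu = mu)
      return(bins)
    }
    if (is.null(treatment_ratios)) {
      treatment_ratios <- rep(1, length(treatments))
    }
    out <- list()
    for (i in seq_along(treatments)) {
      b <- bins
      b$treatment <- treatments[i]
      mu <- b$opportunity * base_rate *
        exp(slope * treatment_ratios[i] * (level - 1))
      b$mutation_count <- rnbinom(n_bins, size = theta, mu = mu)
      out[[i]] <- b
    }
    list_rbind(out)
  })
}
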