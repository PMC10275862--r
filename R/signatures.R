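#' Cosine similarity between two mutation spectra
#'
#' @param a,b Non-negative numeric vectors of equal length, each with at
#'   least one nonzero entry.
#' @return dot(a, b) / (||a|| ||b||), in `[0, 1]` for non-negative input.
#' @export
cosine_similarity <- function(a, b) {
  if (length(a) != length(b)) abort("spectra must have equal length")
  na <- sqrt(sum(a^2))
  nb <- sqrt(sum(b^2))
  if (na == 0 || nb == 0) abort("cosine similarity undefined for a zero vector")
  sum(a * b) / (na * nb)
}

# cosine similarity matrix between columns of A and columns of B
cosine_matrix <- function(A, B) {
  An <- sweep(A, 2, sqrt(colSums(A^2)), "/")
  Bn <- sweep(B, 2, sqrt(colSums(B^2)), "/")
  crossprod(An, Bn)
}

# KL-divergence NMF by multiplicative updates (Lee-Seung); V ~ W H.
# Returns column-normalized W, rescaled H, and the objective trajectory
# (monotone non-increasing up to floating point).
nmf_kl <- function(V, k, max_iter = 1000, tol = 1e-8, seed = NULL) {
  eps <- .Machine$double.eps
  m <- nrow(V)
  n <- ncol(V)
  if (k >= min(m, n)) abort("`k` must be smaller than both catalog dimensions")
  if (all(V == 0)) abort("all-zero catalog")
  kl_div <- function(V, WH) {
    pos <- V > 0
    sum(V[pos] * log(V[pos] / WH[pos])) - sum(V) + sum(WH)
  }
  withr::with_seed(seed, {
    W <- matrix(runif(m * k, 0.1, 1), m, k)
    H <- matrix(runif(k * n, 0.1, 1), k, n)
  })
  WH <- W %*% H
  obj <- kl_div(V, WH)
  trace <- obj
  for (it in seq_len(max_iter)) {
    H <- H * (crossprod(W, V / (WH + eps))) / (colSums(W) + eps)
    WH <- W %*% H
    W <- W * ((V / (WH + eps)) %*% t(H)) /
      matrix(rowSums(H), m, k, byrow = TRUE)
    WH <- W %*% H
    new_obj <- kl_div(V, WH)
    trace <- c(trace, new_obj)
    if (abs(obj - new_obj) <= tol * max(1, abs(obj))) {
      obj <- new_obj
      break
    }
    obj <- new_obj
  }
  scale <- colSums(W)
  W <- sweep(W, 2, scale, "/")
  H <- H * scale
  list(W = W, H = H, objective = obj, trace = trace)
}

# per-clone multinomial bootstrap of a count catalog (column totals kept)
bootstrap_catalog <- function(V) {
  apply(V, 2, function(col) {
    tot <- sum(col)
    if (tot == 0) return(col)
    as.numeric(rmultinom(1, tot, col / tot))
  })
}

# greedy one-to-one matching: assign[i] = column of B matched to column i of A
match_signatures <- function(A, B) {
  k <- ncol(A)
  sim <- cosine_matrix(A, B)
  assign <- integer(k)
  used <- logical(k)
  for (step in seq_len(k)) {
    sim_r <- sim
    sim_r[assign > 0, ] <- -Inf
    sim_r[, used] <- -Inf
    best <- which(sim_r == max(sim_r), arr.ind = TRUE)[1, ]
    assign[best[1]] <- best[2]
    used[best[2]] <- TRUE
  }
  assign
}

# non-negative least-squares exposures of catalog columns on signatures
nnls_exposures <- function(S, V) {
  E <- vapply(seq_len(ncol(V)), function(j) {
    pracma::lsqnonneg(S, V[, j])$x
  }, numeric(ncol(S)))
  E <- matrix(E, nrow = ncol(S))
  dimnames(E) <- list(colnames(S), colnames(V))
  E
}

#' Extract de novo mutational signatures by bootstrapped NMF
#'
#' Factorizes a categories-by-clones count catalog as signatures times
#' exposures using Kullback-Leibler NMF with multiplicative updates. For
#' each candidate rank, `n_replicates` runs are performed on per-clone
#' multinomial bootstrap resamples of the catalog; replicate solutions are
#' matched by cosine similarity to a reference run on the unresampled
#' catalog, and per-signature stability is the mean cosine similarity of
#' matched replicate signatures to their consensus. Rank selection keeps
#' solutions with high stability and low reconstruction error: among ranks
#' with mean stability >= `stability_min`, a larger rank is preferred only
#' when it lowers the relative reconstruction error by at least
#' `error_gain_min` (relative), which guards against stable-but-redundant
#' extra components; if no rank qualifies, the rank with the highest mean
#' stability is used. Final exposures are refit per
#' clone by non-negative least squares against the consensus signatures, so
#' attributed counts sum to approximately the observed counts.
#'
#' @param catalog Count-matrix tibble (see [build_count_matrix()]) or a
#'   numeric matrix with category rownames.
#' @param k_range Integer vector of candidate ranks.
#' @param n_replicates Bootstrap replicates per rank.
#' @param seed Integer seed; the whole extraction is deterministic given it.
#' @param max_iter,tol NMF iteration controls.
#' @param stability_min Mean-stability threshold for rank selection.
#' @param error_gain_min Minimum relative reconstruction-error improvement
#'   required to prefer a larger qualifying rank.
#' @return Object of class `radmut_signatures`: list with `signatures`
#'   (categories x k matrix, columns sum to 1, named `<prefix>A`, ...),
#'   `exposures` (k x clones matrix of attributed counts), `stability`
#'   (per-signature), `reconstruction_error` (relative Frobenius), `k`, and
#'   a per-rank `rank_summary` tibble.
#' @export
extract_signatures <- function(catalog, k_range, n_replicates = 10,
                               seed = NULL, max_iter = 1000, tol = 1e-8,
                               stability_min = 0.8, error_gain_min = 0.05) {
  V <- if (is.matrix(catalog)) catalog else as_count_matrix(catalog)
  if (any(V < 0)) abort("catalog must be non-negative")
  if (max(k_range) >= ncol(V)) {
    abort("max(k_range) must be smaller than the number of clones")
  }
  seeds <- withr::with_seed(seed, {
    sample.int(.Machine$integer.max, length(k_range) * (n_replicates + 1))
  })
  si <- 0L
  next_seed <- function() {
    si <<- si + 1L
    seeds[si]
  }

  fits <- list()
  for (k in k_range) {
    ref <- nmf_kl(V, k, max_iter, tol, seed = next_seed())
    members <- array(NA_real_, dim = c(nrow(V), k, n_replicates))
    for (r in seq_len(n_replicates)) {
      s <- next_seed()
      Vb <- withr::with_seed(s, bootstrap_catalog(V))
      fit <- nmf_kl(Vb, k, max_iter, tol, seed = s + 1)
      idx <- match_signatures(ref$W, fit$W)
      members[, , r] <- fit$W[, idx]
    }
    consensus <- apply(members, c(1, 2), mean)
    consensus <- sweep(consensus, 2, colSums(consensus), "/")
    stability <- vapply(seq_len(k), function(j) {
      mean(vapply(seq_len(n_replicates), function(r) {
        cosine_similarity(members[, j, r], consensus[, j])
      }, numeric(1)))
    }, numeric(1))
    E <- nnls_exposures(consensus, V)
    err <- norm(V - consensus %*% E, "F") / norm(V, "F")
    fits[[as.character(k)]] <- list(k = k, signatures = consensus,
                                    exposures = E, stability = stability,
                                    error = err)
  }

  rank_summary <- list_rbind(map(fits, function(f) {
    tibble(k = f$k, mean_stability = mean(f$stability),
           min_stability = min(f$stability), reconstruction_error = f$error)
  }))
  qual <- rank_summary[rank_summary$mean_stability >= stability_min, ]
  if (nrow(qual)) {
    qual <- qual[order(qual$k), ]
    k_sel <- qual$k[1]
    err_cur <- qual$reconstruction_error[1]
    for (i in seq_len(nrow(qual))[-1]) {
      if (qual$reconstruction_error[i] < err_cur * (1 - error_gain_min)) {
        k_sel <- qual$k[i]
        err_cur <- qual$reconstruction_error[i]
      }
    }
  } else {
    k_sel <- rank_summary$k[which.max(rank_summary$mean_stability)]
  }
  best <- fits[[as.character(k_sel)]]

  prefix <- switch(as.character(nrow(V)), "96" = "SBS96", "83" = "ID83",
                   "6" = "SBS6", "SIG")
  sig_names <- paste0(prefix, LETTERS[seq_len(k_sel)])
  colnames(best$signatures) <- sig_names
  rownames(best$signatures) <- rownames(V)
  rownames(best$exposures) <- sig_names
  names(best$stability) <- sig_names

  structure(
    list(signatures = best$signatures, exposures = best$exposures,
         stability = best$stability, reconstruction_error = best$error,
         k = k_sel, rank_summary = rank_summary, catalog = V),
    class = "radmut_signatures"
  )
}

#' @export
print.radmut_signatures <- function(x, ...) {
  cat("Extracted mutational signatures: k =", x$k, "\n")
  cat("  categories:", nrow(x$signatures), " clones:", ncol(x$exposures), "\n")
  cat("  stability:", paste(sprintf("%s %.3f", names(x$stability),
                                    x$stability), collapse = ", "), "\n")
  cat("  relative reconstruction error:",
      sprintf("%.4f", x$reconstruction_error), "\n")
  invisible(x)
}

#' @export
tidy.radmut_signatures <- function(x, ...) {
  as_tibble(x$signatures, rownames = "category") |>
    tidyr::pivot_longer(-"category", names_to = "signature",
                        values_to = "weight")
}

#' @export
glance.radmut_signatures <- function(x, ...) {
  tibble(k = x$k, mean_stability = mean(x$stability),
         min_stability = min(x$stability),
         reconstruction_error = x$reconstruction_error)
}

#' Per-clone signature exposures as a tibble
#'
#' @param x A `radmut_signatures` object.
#' @return Tibble with `clone_id`, `signature`, `exposure` (attributed
#'   mutation counts).
#' @export
exposures_tbl <- function(x) {
  as_tibble(t(x$exposures), rownames = "clone_id") |>
    tidyr::pivot_longer(-"clone_id", names_to = "signature",
                        values_to = "exposure")
}

#' Assign extracted signatures to reference signatures by cosine similarity
#'
#' Each extracted signature is assigned to its best-matching reference
#' signature when the cosine similarity is at least `threshold` (0.85 by
#' default), and left unassigned otherwise. Ties are broken by
#' lexicographic reference name with a warning.
#'
#' @param extracted A `radmut_signatures` object or a categories x k matrix.
#' @param reference Reference catalog: tibble from
#'   [read_signature_catalog()] or matrix; category order must match.
#' @param threshold Minimum cosine similarity for assignment (inclusive).
#' @return Tibble with `signature`, `best_reference`, `cosine`, `assigned`.
#' @export
assign_to_reference <- function(extracted, reference, threshold = 0.85) {
  S <- if (inherits(extracted, "radmut_signatures")) {
    extracted$signatures
  } else {
    as.matrix(extracted)
  }
  R <- if (is.matrix(reference)) reference else as_count_matrix(reference)
  check_category_order(rownames(S), rownames(R))
  sim <- cosine_matrix(S, R)
  rows <- map(seq_len(ncol(S)), function(i) {
    best <- max(sim[i, ])
    cand <- sort(colnames(R)[sim[i, ] == best])
    if (length(cand) > 1) {
      warn(paste0("cosine tie for ", colnames(S)[i], "; taking ", cand[1]))
    }
    tibble(signature = colnames(S)[i], best_reference = cand[1],
           cosine = best, assigned = best >= threshold)
  })
  list_rbind(rows) |>
    mutate(best_reference = ifelse(.data$assigned, .data$best_reference,
                                   NA_character_))
}

check_category_order <- function(a, b) {
  if (is.null(a) || is.null(b)) return(invisible(TRUE))
  if (length(a) != length(b) || any(a != b)) {
    abort("category order mismatch between spectra and reference catalog")
  }
  invisible(TRUE)
}

#' Decompose a spectrum into a mixture of reference signatures
#'
#' Non-negative least-squares fit of the spectrum as a conic combination of
#' reference signature columns; components contributing less than
#' `min_weight` of the total are pruned and the remainder refit. Weights
#' are normalized to sum to one and the cosine similarity between the
#' original spectrum and its reconstruction is reported.
#'
#' @param spectrum Non-negative numeric vector (one spectrum), optionally
#'   named by category.
#' @param reference Reference catalog (tibble or matrix), category order
#'   matching `spectrum`.
#' @param min_weight Pruning threshold on normalized weights.
#' @param poor_fit_below Reconstruction cosine under which the result is
#'   flagged as a poor fit.
#' @return Object of class `radmut_decomposition`: list with `weights`
#'   (tibble `reference`, `weight`), `cosine`, `poor_fit`, `reconstruction`.
#' @export
decompose_signature <- function(spectrum, reference, min_weight = 0.05,
                                poor_fit_below = 0.9) {
  R <- if (is.matrix(reference)) reference else as_count_matrix(reference)
  if (ncol(R) == 0) abort("empty reference catalog")
  if (!is.null(names(spectrum))) check_category_order(names(spectrum),
                                                      rownames(R))
  v <- as.numeric(spectrum)
  if (length(v) != nrow(R)) abort("spectrum length does not match reference")
  fit <- pracma::lsqnonneg(R, v)$x
  keep <- seq_len(ncol(R))
  w <- fit
  repeat {
    tot <- sum(w)
    if (tot == 0) break
    rel <- w / tot
    drop <- keep[rel < min_weight & w > 0]
    keep2 <- keep[rel >= min_weight]
    if (length(drop) == 0 || length(keep2) == 0) break
    keep <- keep2
    w0 <- pracma::lsqnonneg(R[, keep, drop = FALSE], v)$x
    w <- numeric(ncol(R))
    w[keep] <- w0
    if (all(w[keep] / sum(w) >= min_weight)) break
  }
  recon <- as.numeric(R %*% w)
  cosine <- if (sum(recon) == 0) 0 else cosine_similarity(v, recon)
  weights <- tibble(reference = colnames(R), weight = w) |>
    filter(.data$weight > 0) |>
    mutate(weight = .data$weight / sum(.data$weight)) |>
    arrange(desc(.data$weight))
  structure(
    list(weights = weights, cosine = cosine,
         poor_fit = cosine < poor_fit_below, reconstruction = recon),
    class = "radmut_decomposition"
  )
}

#' @export
print.radmut_decomposition <- function(x, ...) {
  cat("Signature decomposition (reconstruction cosine ",
      sprintf("%.3f", x$cosine),
      if (x$poor_fit) ", poor fit" else "", ")\n", sep = "")
  print(x$weights)
  invisible(x)
}

#' @export
tidy.radmut_decomposition <- function(x, ...) x$weights

#' @export
glance.radmut_decomposition <- function(x, ...) {
  tibble(n_components = nrow(x$weights), cosine = x$cosine,
         poor_fit = x$poor_fit)
}

#' Robustness of extracted signatures to subsampling of external datasets
#'
#' The pooled extraction catalog combines the cohort's own clones with
#' external datasets. For each repeat, a fraction of each external
#' dataset's columns is removed uniformly at random, signatures are
#' re-extracted from the remaining catalog, and each original signature is
#' matched to its best re-extracted counterpart by cosine similarity; the
#' correlation of exposures over the cohort's own clones is also reported.
#'
#' @param own Count matrix (tibble or matrix) of the cohort's own clones.
#' @param externals Named list of external count matrices (same categories).
#' @param fraction Fraction of each external dataset's columns removed per
#'   repeat.
#' @param n_repeats Number of subsampling repeats.
#' @param k_range,n_replicates,seed Passed to [extract_signatures()].
#' @return List with `original` (the full-catalog `radmut_signatures`) and
#'   `report`, a tibble with one row per repeat and original signature:
#'   `repeat_id`, `signature`, `best_cosine`, `exposure_cor`.
#' @export
subsample_robustness <- function(own, externals = list(), fraction = 0.5,
                                 n_repeats = 3, k_range, n_replicates = 10,
                                 seed = NULL) {
  own_m <- if (is.matrix(own)) own else as_count_matrix(own)
  ext_m <- map(externals, function(e) if (is.matrix(e)) e else as_count_matrix(e))
  for (e in ext_m) {
    if (ncol(e) < 2) abort("each external dataset needs >= 2 columns")
    check_category_order(rownames(own_m), rownames(e))
  }
  pooled <- do.call(cbind, c(list(own_m), unname(ext_m)))
  seeds <- withr::with_seed(seed, sample.int(.Machine$integer.max,
                                             n_repeats + 1))
  original <- extract_signatures(pooled, k_range, n_replicates,
                                 seed = seeds[1])
  own_ids <- colnames(own_m)

  rows <- list()
  for (r in seq_len(n_repeats)) {
    kept <- withr::with_seed(seeds[r + 1], {
      map(ext_m, function(e) {
        drop_n <- floor(fraction * ncol(e))
        if (drop_n == 0) return(e)
        keep <- sort(sample.int(ncol(e), ncol(e) - drop_n))
        e[, keep, drop = FALSE]
      })
    })
    sub <- do.call(cbind, c(list(own_m), unname(kept)))
    # same extraction seed as the original run, so that with nothing removed
    # (no externals, or fraction 0) the re-extraction is identical to it
    refit <- extract_signatures(sub, k_range, n_replicates, seed = seeds[1])
    sim <- cosine_matrix(original$signatures, refit$signatures)
    for (j in seq_len(ncol(original$signatures))) {
      best <- which.max(sim[j, ])
      e_cor <- suppressWarnings(
        cor(original$exposures[j, own_ids], refit$exposures[best, own_ids])
      )
      rows[[length(rows) + 1]] <- tibble(
        repeat_id = r, signature = colnames(original$signatures)[j],
        best_match = colnames(refit$signatures)[best],
        best_cosine = max(sim[j, ]), exposure_cor = e_cor)
    }
  }
  list(original = original, report = list_rbind(rows))
}

#' Read or write a signature catalog TSV
#'
#' Catalogs are TSV files with category labels in the first column and one
#' named signature per remaining column (the COSMIC download layout).
#'
#' @param path File path.
#' @return Tibble with `category` first.
#' @export
read_signature_catalog <- function(path) {
  out <- readr::read_tsv(path, show_col_types = FALSE)
  names(out)[1] <- "category"
  out
}

#' @rdname read_signature_catalog
#' @param catalog Count-matrix or signature tibble (category column first).
#' @export
write_signature_catalog <- function(catalog, path) {
  readr::write_tsv(as_tibble(catalog), path)
  invisible(path)
}
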