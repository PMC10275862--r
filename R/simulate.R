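#' Built-in simulation signature spectra
#'
#' Three SBS96 spectra used as ground truth by the cohort simulator,
#' loosely emulating the dominant processes seen in cultured cell lines:
#' an oxidative-damage-like C>A spectrum, a clock-like C>T spectrum with
#' extra weight at NCG contexts, and a broad T>C transition spectrum. The
#' spectra are deliberately well separated (pairwise cosine < 0.2) so that
#' factorization truth is unambiguous. Columns sum to 1.
#'
#' @return 96 x 3 matrix with rownames `sbs96_categories()`.
#' @export
default_sim_spectra <- function() {
  cats <- sbs96_categories()
  sub <- sub("^.\\[(.>.)\\].$", "\\1", cats)
  up <- substr(cats, 1, 1)
  down <- substr(cats, 7, 7)
  oxid <- ifelse(sub == "C>A", 1, 0.02) * ifelse(up %in% c("A", "T"), 1.6, 1)
  clock <- ifelse(sub == "C>T", 1, 0.02) * ifelse(down == "G", 3, 1)
  trans <- ifelse(sub == "T>C", 1, 0.02) * ifelse(up == "A", 1.8, 1)
  m <- cbind(oxidative_CA = oxid / sum(oxid),
             clock_CT = clock / sum(clock),
             transition_TC = trans / sum(trans))
  rownames(m) <- cats
  m
}

#' @rdname default_sim_spectra
#' @details `default_cluster_spectrum()` is the 6-class spectrum of
#'   injected mutation clusters: C>T dominated with a T>A component, i.e.
#'   distinct from the C>A-rich genome-wide background, mirroring how
#'   clustered and unclustered spectra differ.
#' @export
default_cluster_spectrum <- function() {
  c("C>A" = 0.05, "C>G" = 0.10, "C>T" = 0.55, "T>A" = 0.20,
    "T>C" = 0.05, "T>G" = 0.05)
}

# ID83 category mixes used by the simulator; only categories for which the
# placement engine can find sites in a random toy genome.
default_del_categories <- function() {
  c("1:Del:T:1" = 0.10, "1:Del:T:2" = 0.10, "1:Del:T:4" = 0.08,
    "1:Del:T:5" = 0.12, "1:Del:C:1" = 0.08, "1:Del:C:2" = 0.06,
    "2:Del:R:0" = 0.12, "3:Del:R:0" = 0.08, "2:Del:R:1" = 0.04,
    "5:Del:R:0" = 0.06, "2:Del:M:1" = 0.06, "3:Del:M:1" = 0.04,
    "3:Del:M:2" = 0.02, "4:Del:M:1" = 0.02, "5:Del:M:1" = 0.02)
}

default_ins_categories <- function() {
  c("1:Ins:T:0" = 0.15, "1:Ins:T:1" = 0.15, "1:Ins:T:4" = 0.10,
    "1:Ins:T:5" = 0.20, "1:Ins:C:0" = 0.10, "1:Ins:C:1" = 0.10,
    "2:Ins:R:0" = 0.12, "3:Ins:R:0" = 0.08)
}

#' Default simulated cohort design
#'
#' Mirrors the shape of a three-cell-line particle-irradiation experiment:
#' for each of three cell lines (with haploid, diploid-heterozygous and
#' tetraploid-heterozygous VAF models), one sham-irradiated control clone,
#' two helium-irradiated and four proton-irradiated clones — 21 clones in
#' all. Per-clone burdens are of the order of 10^3 SNVs and 10^2 small
#' indels; treated clones carry a higher deletion:insertion ratio, shorter
#' SVs, more deletion SVs and injected mutation clusters (pairs plus
#' kataegis-like showers, more in helium), so that the treatment effects
#' the pipeline is meant to detect are present by construction.
#'
#' @param depth Sequencing depth used for read simulation.
#' @return List with `layout` (chromosome lengths), `gc_fraction`, `depth`
#'   and a `clones` tibble (one row per clone with burden, exposure,
#'   cluster and SV parameters).
#' @export
default_design <- function(depth = 40) {
  lines <- tibble(
    cell_line = c("lineA", "lineB", "lineC"),
    ploidy = c("diploid-het", "haploid", "tetraploid-het")
  )
  per_line <- function(cell_line, ploidy) {
    trt <- c("control", "helium", "helium", rep("proton", 4))
    n <- length(trt)
    idx <- stats::ave(seq_len(n), trt, FUN = seq_along)
    snv <- c(control = 900, helium = 1000, proton = 1100)[trt] + 30 * (idx - 1)
    ndel <- c(control = 60, helium = 90, proton = 150)[trt] + 5 * (idx - 1)
    nins <- c(control = 40, helium = 45, proton = 50)[trt]
    # signature activity differs mainly by cell line (as it does between
    # real lines), with a mild oxidative shift in proton-treated clones
    base_mix <- switch(cell_line,
      lineA = c(oxidative_CA = 0.60, clock_CT = 0.25, transition_TC = 0.15),
      lineB = c(oxidative_CA = 0.30, clock_CT = 0.55, transition_TC = 0.15),
      c(oxidative_CA = 0.25, clock_CT = 0.20, transition_TC = 0.55))
    tweak <- function(shift) {
      m <- base_mix + c(shift, 0, 0)
      m / sum(m)
    }
    exposures <- list(control = tweak(0), helium = tweak(0.03),
                      proton = tweak(0.06))
    clusters <- list(
      control = tibble(n = integer(0), size = integer(0), span = integer(0)),
      helium = tibble(n = c(25L, 3L), size = c(2L, 7L), span = c(600L, 3000L)),
      proton = tibble(n = c(15L, 1L), size = c(2L, 6L), span = c(600L, 2500L))
    )
    tibble(
      clone_id = paste0(cell_line, "_", trt, idx),
      cell_line = cell_line,
      treatment = trt,
      ploidy = ploidy,
      n_snv = as.integer(snv),
      n_del = as.integer(ndel),
      n_ins = as.integer(nins),
      n_sv_del = c(control = 4L, helium = 8L, proton = 9L)[trt],
      n_sv_ins = 2L,
      n_sv_dup = 4L,
      n_sv_inv = c(control = 3L, helium = 4L, proton = 3L)[trt],
      sv_meanlog = c(control = 9.3, helium = 9.0, proton = 8.3)[trt],
      exposures = exposures[trt],
      clusters = clusters[trt]
    )
  }
  clones <- list_rbind(pmap(lines, per_line))
  list(
    layout = c(chr1 = 8e6, chr2 = 4e6),
    gc_fraction = 0.42,
    depth = depth,
    clones = clones
  )
}

#' Generate a random toy genome
#'
#' Random sequence with the requested GC fraction. For sequences of at
#' least 10 kb the generator checks that all 64 trinucleotides occur and
#' regenerates (new derived seed) if any is absent, so context-matched
#' mutation placement cannot fail.
#'
#' @param layout Named numeric vector of chromosome lengths (>= 1000).
#' @param gc_fraction Target GC content.
#' @param seed Integer seed; output is deterministic given it.
#' @return Named character vector of sequences.
#' @export
make_toy_genome <- function(layout, gc_fraction = 0.41, seed = NULL) {
  if (any(layout < 1000)) abort("chromosome lengths must be >= 1000")
  bases <- charToRaw("ACGT")
  p <- c((1 - gc_fraction) / 2, gc_fraction / 2, gc_fraction / 2,
         (1 - gc_fraction) / 2)
  withr::with_seed(seed, {
    out <- vapply(layout, function(len) {
      for (attempt in 1:10) {
        s <- rawToChar(bases[sample.int(4, len, replace = TRUE, prob = p)])
        if (len < 10000 || all_trinucs_present(s)) return(s)
      }
      abort("failed to generate a sequence containing all trinucleotides")
    }, character(1))
    names(out) <- names(layout)
    out
  })
}

all_trinucs_present <- function(s) {
  probe <- substring(s, seq(1, min(nchar(s), 200000) - 2),
                     seq(3, min(nchar(s), 200000)))
  if (length(unique(probe)) >= 64) return(TRUE)
  full <- substring(s, seq_len(nchar(s) - 2), seq_len(nchar(s) - 2) + 2)
  length(unique(full)) >= 64
}

# ---- site selection -------------------------------------------------------

new_used_sites <- function() new.env(parent = emptyenv())

is_used <- function(used, chrom, pos) {
  any(vapply(pos, function(p) {
    !is.null(used[[paste0(chrom, ":", p)]])
  }, logical(1)))
}

mark_used <- function(used, chrom, pos) {
  for (p in pos) used[[paste0(chrom, ":", p)]] <- TRUE
  invisible(used)
}

# context label (pyrimidine-folded trinucleotide) of positions on one chrom
folded_context <- function(seq, pos) {
  ctx <- substr(rep(seq, length(pos)), pos - 1L, pos + 1L)
  mid <- substr(ctx, 2L, 2L)
  pur <- mid %in% c("A", "G")
  ctx[pur] <- revcomp(ctx[pur])
  ctx
}

# draw genomic sites whose folded trinucleotide context matches each needed
# SBS96 category; returns tibble(chrom, pos, ref, alt, category)
sample_snv_sites <- function(genome, categories, used) {
  needed <- table(categories)
  lens <- nchar(genome)
  total <- sum(needed)
  out <- vector("list", 0)
  guard <- 0L
  while (total > 0 && guard < 200) {
    guard <- guard + 1L
    batch <- max(2000L, 50L * total)
    ch_idx <- sample.int(length(genome), batch, replace = TRUE,
                         prob = lens / sum(lens))
    pos <- 1L + floor(runif(batch) * (lens[ch_idx] - 2L))
    pos <- pmax(pos, 2L)
    cand <- tibble(chrom = names(genome)[ch_idx], pos = as.integer(pos))
    cand <- distinct(cand, .data$chrom, .data$pos)
    ctx <- character(nrow(cand))
    for (ch in unique(cand$chrom)) {
      i <- cand$chrom == ch
      ctx[i] <- folded_context(genome[[ch]], cand$pos[i])
    }
    cand$ctx <- ctx
    for (cat in names(needed)[needed > 0]) {
      want_ctx <- paste0(substr(cat, 1, 1), substr(cat, 3, 3),
                         substr(cat, 7, 7))
      hits <- which(cand$ctx == want_ctx)
      if (length(hits) == 0) next
      take <- head(hits, needed[[cat]])
      keep <- take[!vapply(take, function(i) {
        is_used(used, cand$chrom[i], cand$pos[i])
      }, logical(1))]
      if (length(keep) == 0) next
      rows <- cand[keep, c("chrom", "pos")]
      rows$category <- cat
      for (i in seq_len(nrow(rows))) {
        mark_used(used, rows$chrom[i], rows$pos[i])
      }
      out[[length(out) + 1]] <- rows
      needed[[cat]] <- needed[[cat]] - nrow(rows)
    }
    total <- sum(needed)
  }
  if (total > 0) {
    abort(paste0("could not place SNVs for categories: ",
                 paste(names(needed)[needed > 0], collapse = ", ")))
  }
  sites <- list_rbind(out)
  # derive ref/alt on the + strand from the pyrimidine-strand category
  ref <- alt <- character(nrow(sites))
  for (ch in unique(sites$chrom)) {
    i <- sites$chrom == ch
    ref[i] <- substr(rep(genome[[ch]], sum(i)), sites$pos[i], sites$pos[i])
  }
  cat_ref <- substr(sites$category, 3, 3)
  cat_alt <- substr(sites$category, 5, 5)
  on_pyr <- ref == cat_ref
  alt[on_pyr] <- cat_alt[on_pyr]
  alt[!on_pyr] <- unname(COMPLEMENT[cat_alt[!on_pyr]])
  sites$ref <- ref
  sites$alt <- alt
  sites
}

# homopolymer runs of `base` with exact length n (n <= 5) or >= n (n = 6)
find_runs <- function(seq, base, n, at_least = FALSE) {
  pat <- if (at_least) {
    paste0("(?<!", base, ")", base, "{", n, ",}(?!", base, ")")
  } else {
    paste0("(?<!", base, ")", base, "{", n, "}(?!", base, ")")
  }
  m <- gregexpr(pat, seq, perl = TRUE)[[1]]
  if (m[1] == -1) return(list(start = integer(0), len = integer(0)))
  list(start = as.integer(m), len = attr(m, "match.length"))
}

cached_runs <- function(run_cache, genome, ch, base, run_len, at_least) {
  key <- paste(ch, base, run_len, at_least, sep = "|")
  if (is.null(run_cache[[key]])) {
    run_cache[[key]] <- find_runs(genome[[ch]], base, run_len, at_least)
  }
  run_cache[[key]]
}

# place `n_events` indels of one ID83 category; returns a tibble (possibly
# short of n_events when sites for a rare category are exhausted)
place_indel_category <- function(genome, category, n_events, used, run_cache,
                                 max_tries = 400) {
  if (n_events == 0) return(NULL)
  parts <- strsplit(category, ":", fixed = TRUE)[[1]]
  L <- as.integer(parts[1])
  kind <- parts[2]
  sub3 <- parts[3]
  d <- as.integer(parts[4])
  chrs <- names(genome)
  wts <- nchar(genome) / sum(nchar(genome))
  out_pos <- integer(0)
  out_chrom <- out_ref <- out_alt <- character(0)
  add <- function(ch, p, ref, alt) {
    out_chrom <<- c(out_chrom, ch)
    out_pos <<- c(out_pos, p)
    out_ref <<- c(out_ref, ref)
    out_alt <<- c(out_alt, alt)
  }

  if (L == 1L) {
    for (ev in seq_len(n_events)) {
      base <- if (runif(1) < 0.5) sub3 else COMPLEMENT[[sub3]]
      ch <- chrs[sample.int(length(chrs), 1, prob = wts)]
      seq <- genome[[ch]]
      if (kind == "Ins" && d == 0L) {
        for (t in seq_len(max_tries)) {
          p <- 1L + floor(runif(1) * (nchar(seq) - 3L))
          if (substr(seq, p, p) != base &&
              substr(seq, p + 1L, p + 1L) != base &&
              !is_used(used, ch, c(p, p + 1L))) {
            anchor <- substr(seq, p, p)
            mark_used(used, ch, c(p, p + 1L))
            add(ch, p, anchor, paste0(anchor, base))
            break
          }
        }
        next
      }
      run_len <- if (kind == "Del") d + 1L else d
      at_least <- d == 5L
      runs <- cached_runs(run_cache, genome, ch, base, run_len, at_least)
      nr <- length(runs$start)
      if (nr == 0) next
      for (t in seq_len(min(max_tries, 60L))) {
        i <- sample.int(nr, 1)
        st <- runs$start[i]
        if (st <= 1L) next
        p <- st - 1L
        span <- p:(st + runs$len[i])
        if (is_used(used, ch, span)) next
        anchor <- substr(seq, p, p)
        mark_used(used, ch, span)
        if (kind == "Del") {
          add(ch, p, paste0(anchor, base), anchor)
        } else {
          add(ch, p, anchor, paste0(anchor, base))
        }
        break
      }
    }
  } else {
    # rejection sampling, each candidate verified against the classifier
    placed <- 0L
    tries <- 0L
    budget <- max_tries * n_events
    while (placed < n_events && tries < budget) {
      tries <- tries + 1L
      ch <- chrs[sample.int(length(chrs), 1, prob = wts)]
      seq <- genome[[ch]]
      L_act <- if (L == 5L) 4L + sample.int(3L, 1) else L
      if (kind == "Del") {
        s <- L_act + 6L + floor(runif(1) * (nchar(seq) - 3L * L_act - 20L))
        p <- s - 1L
        ref <- substr(seq, p, s + L_act - 1L)
        alt <- substr(seq, p, p)
      } else {
        p <- 6L + floor(runif(1) * (nchar(seq) - L_act - 20L))
        ref <- substr(seq, p, p)
        ins <- rawToChar(charToRaw("ACGT")[sample.int(4, L_act,
                                                      replace = TRUE)])
        alt <- paste0(ref, ins)
      }
      lab <- tryCatch(id83_label_one(seq, p, ref, alt, 100L),
                      error = function(e) NA_character_)
      if (is.na(lab) || lab != category) next
      span <- p:(p + nchar(ref))
      if (is_used(used, ch, span)) next
      mark_used(used, ch, span)
      add(ch, p, ref, alt)
      placed <- placed + 1L
    }
  }
  if (length(out_pos) == 0) return(NULL)
  tibble(chrom = out_chrom, pos = out_pos, ref = out_ref, alt = out_alt,
         category_true = category)
}

# pick positions for one injected cluster: `size` mutations within `span`
place_cluster <- function(genome, size, span, spectrum6, used,
                          max_tries = 200) {
  ch <- sample(names(genome), 1, prob = nchar(genome) / sum(nchar(genome)))
  seq <- genome[[ch]]
  step <- span / (size - 1)
  for (t in seq_len(max_tries)) {
    w0 <- sample.int(nchar(seq) - span - 100L, 1) + 50L
    types <- sample(names(spectrum6), size, replace = TRUE, prob = spectrum6)
    need_pyr <- substr(types, 1, 1) # C or T on the pyrimidine strand
    pos <- integer(size)
    ok <- TRUE
    for (i in seq_len(size)) {
      target <- w0 + round((i - 1) * step)
      hit <- NA_integer_
      for (off in 0:30) {
        for (p in unique(c(target + off, target - off))) {
          b <- substr(seq, p, p)
          pyr <- if (b %in% c("A", "G")) COMPLEMENT[[b]] else b
          if (pyr == need_pyr[i] && !is_used(used, ch, p) &&
              !(p %in% pos[seq_len(i - 1)])) {
            hit <- p
            break
          }
        }
        if (!is.na(hit)) break
      }
      if (is.na(hit)) {
        ok <- FALSE
        break
      }
      pos[i] <- hit
    }
    if (!ok) next
    mark_used(used, ch, pos)
    ref <- vapply(pos, function(p) substr(seq, p, p), character(1))
    alt_pyr <- substr(types, 3, 3)
    alt <- ifelse(ref %in% c("C", "T"), alt_pyr,
                  unname(COMPLEMENT[alt_pyr]))
    return(tibble(chrom = ch, pos = sort(pos),
                  ref = ref[order(pos)], alt = alt[order(pos)],
                  sbs6_true = types[order(pos)]))
  }
  abort("could not place an injected cluster")
}

ploidy_vaf <- function(ploidy) {
  switch(ploidy,
         "haploid" = 1.0,
         "diploid-het" = 0.5,
         "tetraploid-het" = 0.25,
         abort(paste0("unknown ploidy model: ", ploidy)))
}

# read evidence for one attributed variant
draw_reads <- function(n, vaf, depth) {
  alt <- rbinom(n, depth, vaf)
  pmin(pmax(alt, 2L), depth) # keep >= 2 alt reads so calls are filterable
}

#' Simulate the mutations of one clone
#'
#' Background SNVs are drawn category-first from the exposure-weighted
#' mixture of signature spectra, then placed at genome sites whose
#' trinucleotide context matches (sampling without replacement). Mutation
#' clusters are injected as `size` mutations within `span` bp with their
#' own 6-class spectrum. Indels are drawn from ID83 category mixes and
#' placed at sequence-compatible sites (homopolymer runs located by exact
#' search; longer events validated against the classifier at placement).
#' SVs are drawn per class with lognormal lengths. Read evidence is
#' binomial at the configured depth with mean VAF set by the ploidy model
#' (1.0 haploid, 0.5 diploid-het, 0.25 tetraploid-het).
#'
#' @param genome Named character vector from [make_toy_genome()].
#' @param clone One-row design entry (see [default_design()]`$clones`).
#' @param spectra Categories x signatures matrix of SBS96 spectra.
#' @param depth Sequencing depth.
#' @param used Shared used-site registry (one per cohort), from
#'   `new_used_sites()`; pass `NULL` for a fresh one.
#' @param cluster_spectrum 6-class spectrum for injected clusters.
#' @param seed Integer seed.
#' @return Tibble of variant records with truth columns (`category_true`,
#'   `sbs6_true`, `cluster_id`, `vaf_true`).
#' @export
simulate_clone <- function(genome, clone, spectra = default_sim_spectra(),
                           depth = 40, used = NULL,
                           cluster_spectrum = default_cluster_spectrum(),
                           seed = NULL, run_cache = NULL) {
  if (is.null(used)) used <- new_used_sites()
  if (is.null(run_cache)) run_cache <- new.env(parent = emptyenv())
  clone <- as.list(as_tibble(clone)[1, ])
  exposures <- clone$exposures[[1]]
  clusters <- clone$clusters[[1]]
  if (abs(sum(exposures) - 1) > 1e-6) abort("clone exposures must sum to 1")
  vaf <- ploidy_vaf(clone$ploidy)

  withr::with_seed(seed, {
    mix <- as.numeric(spectra[, names(exposures)] %*% exposures)
    cats <- sample(rownames(spectra), clone$n_snv, replace = TRUE, prob = mix)
    snv <- sample_snv_sites(genome, cats, used)
    snv <- snv |>
      mutate(var_class = "SNV", category_true = .data$category,
             cluster_id = NA_character_) |>
      select(-"category")

    clu <- list()
    ci <- 0L
    if (nrow(clusters)) {
      for (r in seq_len(nrow(clusters))) {
        for (rep_i in seq_len(clusters$n[r])) {
          ci <- ci + 1L
          cl <- place_cluster(genome, clusters$size[r], clusters$span[r],
                              cluster_spectrum, used)
          cl$var_class <- "SNV"
          cl$category_true <- NA_character_
          cl$cluster_id <- paste0(clone$clone_id, "_clu", ci)
          clu[[ci]] <- select(cl, -"sbs6_true")
        }
      }
    }
    snvs <- bind_rows(c(list(snv), clu))

    indel_rows <- list()
    for (side in c("del", "ins")) {
      n_ev <- if (side == "del") clone$n_del else clone$n_ins
      dist <- if (side == "del") default_del_categories() else default_ins_categories()
      cats_i <- sample(names(dist), n_ev, replace = TRUE, prob = dist)
      for (cat in unique(cats_i)) {
        # rare categories may fall short when sites are exhausted
        hit <- place_indel_category(genome, cat, sum(cats_i == cat),
                                    used, run_cache)
        if (is.null(hit)) next
        hit$var_class <- if (side == "del") "DEL" else "INS"
        hit$cluster_id <- NA_character_
        indel_rows[[length(indel_rows) + 1]] <- hit
      }
    }
    indels <- bind_rows(indel_rows)

    sv_rows <- list()
    for (svc in c("DEL", "INS", "DUP", "INV")) {
      n_ev <- clone[[paste0("n_sv_", tolower(svc))]]
      for (i in seq_len(n_ev)) {
        len <- max(50L, round(rlnorm(1, clone$sv_meanlog, 0.8)))
        ch <- sample(names(genome), 1, prob = nchar(genome) / sum(nchar(genome)))
        p <- sample.int(nchar(genome[[ch]]) - len - 1000L, 1) + 500L
        if (is_used(used, ch, p)) next
        mark_used(used, ch, p)
        resolved <- svc != "INS" || runif(1) < 0.7
        sv_rows[[length(sv_rows) + 1]] <- tibble(
          chrom = ch, pos = p, ref = substr(genome[[ch]], p, p),
          alt = paste0("<", svc, ">"),
          var_class = paste0("SV_", svc),
          sv_end = if (svc == "INS") p + 1 else p + len,
          ins_len = if (svc == "INS" && resolved) len else NA_real_,
          category_true = svc, cluster_id = NA_character_)
      }
    }
    svs <- bind_rows(sv_rows)

    out <- bind_rows(snvs, indels, svs) |>
      mutate(clone_id = clone$clone_id,
             cell_line = clone$cell_line,
             treatment = clone$treatment,
             vaf_true = vaf,
             depth = depth,
             alt_reads = draw_reads(n(), vaf, depth),
             genotype_quality = 60L,
             split_reads = ifelse(startsWith(.data$var_class, "SV_"),
                                  pmax(2L, rbinom(n(), round(depth / 2), vaf)),
                                  NA_integer_))
    if (!"sv_end" %in% names(out)) out$sv_end <- NA_real_
    if (!"ins_len" %in% names(out)) out$ins_len <- NA_real_
    arrange(out, .data$chrom, .data$pos)
  })
}
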