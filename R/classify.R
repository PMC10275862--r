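#' Mutation category schemes
#'
#' Canonical category orderings used throughout the package. The SBS96 order
#' groups the 16 trinucleotide contexts (5' base A,C,G,T then 3' base
#' A,C,G,T) within each of the six pyrimidine-strand substitution types; the
#' ID83 order follows the COSMIC indel catalog layout (1 bp deletions, 1 bp
#' insertions, longer deletions at repeats, longer insertions at repeats,
#' then microhomology-flanked deletions). Reference catalogs supplied to the
#' signature functions must use the same row order.
#'
#' @return Character vector of category labels.
#' @export
sbs6_types <- function() {
  c("C>A", "C>G", "C>T", "T>A", "T>C", "T>G")
}

#' @rdname sbs6_types
#' @export
sbs96_categories <- function() {
  bases <- c("A", "C", "G", "T")
  unlist(lapply(sbs6_types(), function(sub) {
    unlist(lapply(bases, function(up) paste0(up, "[", sub, "]", bases)))
  }))
}

#' @rdname sbs6_types
#' @export
id83_categories <- function() {
  c(
    paste0("1:Del:C:", 0:5), paste0("1:Del:T:", 0:5),
    paste0("1:Ins:C:", 0:5), paste0("1:Ins:T:", 0:5),
    paste0(rep(2:5, each = 6), ":Del:R:", 0:5),
    paste0(rep(2:5, each = 6), ":Ins:R:", 0:5),
    "2:Del:M:1",
    paste0("3:Del:M:", 1:2),
    paste0("4:Del:M:", 1:3),
    paste0("5:Del:M:", 1:5)
  )
}

COMPLEMENT <- c(A = "T", C = "G", G = "C", T = "A")

# reverse complement of a vector of sequences
revcomp <- function(x) {
  vapply(strsplit(chartr("ACGT", "TGCA", x), ""), function(b) {
    paste(rev(b), collapse = "")
  }, character(1))
}

#' Classify SNVs into the six pyrimidine-strand substitution types
#'
#' Purine-reference changes are reverse-complemented so that mutations are
#' tallied DNA strand-symmetrically (e.g. G>T becomes C>A).
#'
#' @param ref,alt Character vectors of single reference/alternate bases.
#' @return Character vector of types among `sbs6_types()`.
#' @export
#' @examples
#' classify_snv_6(c("G", "C", "A"), c("T", "T", "G"))
classify_snv_6 <- function(ref, alt) {
  ref <- toupper(ref)
  alt <- toupper(alt)
  ok <- ref %in% names(COMPLEMENT) & alt %in% names(COMPLEMENT)
  if (!all(ok)) abort("non-ACGT base in `ref` or `alt`")
  if (any(ref == alt)) abort("`ref` and `alt` must differ")
  pur <- ref %in% c("A", "G")
  r <- ifelse(pur, COMPLEMENT[ref], ref)
  a <- ifelse(pur, COMPLEMENT[alt], alt)
  paste0(r, ">", a)
}

#' Classify SNVs into the 96 trinucleotide-context categories
#'
#' Looks up the reference trinucleotide context around each variant, checks
#' that the genome base matches the VCF REF allele, and normalizes to the
#' pyrimidine strand, yielding labels of the form `A[C>A]A`.
#'
#' @param variants Data frame with columns `chrom`, `pos` (1-based), `ref`,
#'   `alt`; extra columns are carried through.
#' @param genome Named character vector (or `DNAStringSet`) of chromosome
#'   sequences covering every variant position with one flanking base.
#' @return `variants` as a tibble with added columns `sbs6` and `sbs96`.
#' @export
classify_snv_96 <- function(variants, genome) {
  genome <- as_genome(genome)
  variants <- as_tibble(variants)
  if (nrow(variants) == 0) {
    return(mutate(variants, sbs6 = character(0), sbs96 = character(0)))
  }
  missing_chrom <- setdiff(unique(variants$chrom), names(genome))
  if (length(missing_chrom)) {
    abort(paste0("chromosomes absent from genome: ",
                 paste(missing_chrom, collapse = ", ")))
  }
  seq <- unname(genome[variants$chrom])
  if (any(variants$pos < 2L | variants$pos > nchar(seq) - 1L)) {
    abort("variant position lacks a flanking base within its contig")
  }
  ctx <- substr(seq, variants$pos - 1L, variants$pos + 1L)
  mid <- substr(ctx, 2L, 2L)
  ref <- toupper(variants$ref)
  alt <- toupper(variants$alt)
  bad <- mid != ref
  if (any(bad)) {
    abort(paste0("genome base does not match REF at ",
                 variants$chrom[bad][1], ":", variants$pos[bad][1]))
  }
  pur <- ref %in% c("A", "G")
  ctx[pur] <- revcomp(ctx[pur])
  sub <- classify_snv_6(ref, alt)
  lab <- paste0(substr(ctx, 1, 1), "[", sub, "]", substr(ctx, 3, 3))
  mutate(variants, sbs6 = sub, sbs96 = lab)
}

# count identical bases walking outward from `from` in direction `dir`
run_count <- function(seq, from, dir, base) {
  n <- 0L
  i <- from
  len <- nchar(seq)
  while (i >= 1L && i <= len && substr(seq, i, i) == base) {
    n <- n + 1L
    i <- i + dir
  }
  n
}

# count exact tandem copies of `motif` starting at `from` going in `dir`
# (dir = +1: copies at from, from+L, ...; dir = -1: copies ending at from)
copy_count <- function(seq, from, dir, motif) {
  L <- nchar(motif)
  len <- nchar(seq)
  n <- 0L
  i <- if (dir > 0) from else from - L + 1L
  while (i >= 1L && i + L - 1L <= len && substr(seq, i, i + L - 1L) == motif) {
    n <- n + 1L
    i <- i + dir * L
  }
  n
}

# longest shared prefix length of two strings, capped at `cap`
shared_prefix <- function(a, b, cap) {
  n <- 0L
  m <- min(nchar(a), nchar(b), cap)
  while (n < m && substr(a, n + 1L, n + 1L) == substr(b, n + 1L, n + 1L)) {
    n <- n + 1L
  }
  n
}

# ID83 label for one left-normalized indel; seq is the chromosome string.
id83_label_one <- function(seq, pos, ref, alt, max_len) {
  lr <- nchar(ref)
  la <- nchar(alt)
  if (lr == la) abort("not an indel: ref and alt have equal length")
  is_del <- lr > la
  if (substr(seq, pos, pos + lr - 1L) != ref) {
    abort(paste0("genome sequence does not match REF at position ", pos))
  }
  if (substr(ref, 1L, min(lr, la)) != substr(alt, 1L, min(lr, la))) {
    abort("indel ref/alt must share their leading anchor bases")
  }
  L <- abs(lr - la)
  if (L > max_len) abort(paste0("indel longer than max_len at position ", pos))

  if (is_del) {
    s <- pos + la       # first deleted base (1-based)
    e <- pos + lr - 1L  # last deleted base
    # left-normalize: deleting [s-1, e-1] yields the same haplotype when the
    # base entering on the right equals the base leaving on the left
    while (s > 1L && substr(seq, s - 1L, s - 1L) == substr(seq, e, e)) {
      s <- s - 1L
      e <- e - 1L
    }
    del <- substr(seq, s, e)
    if (L == 1L) {
      b <- del
      run <- 1L + run_count(seq, s - 1L, -1L, b) + run_count(seq, e + 1L, 1L, b)
      ch <- if (b %in% c("C", "T")) b else COMPLEMENT[[b]]
      return(paste0("1:Del:", ch, ":", min(run - 1L, 5L)))
    }
    extra <- copy_count(seq, e + 1L, 1L, del) + copy_count(seq, s - 1L, -1L, del)
    lb <- min(L, 5L)
    if (extra >= 1L) return(paste0(lb, ":Del:R:", min(extra, 5L)))
    cap <- min(L - 1L, 5L)
    right <- substr(seq, e + 1L, min(nchar(seq), e + L))
    mh_r <- shared_prefix(del, right, cap)
    left <- substr(seq, max(1L, s - L), s - 1L)
    # suffix of the deleted sequence against the sequence immediately before it
    mh_l <- shared_prefix(
      paste(rev(strsplit(del, "")[[1]]), collapse = ""),
      paste(rev(strsplit(left, "")[[1]]), collapse = ""),
      cap
    )
    mh <- max(mh_r, mh_l)
    if (mh >= 1L) return(paste0(lb, ":Del:M:", mh))
    return(paste0(lb, ":Del:R:0"))
  }

  # insertion of S between p and p + 1
  S <- substr(alt, lr + 1L, la)
  p <- pos + lr - 1L
  while (p >= 1L && substr(seq, p, p) == substr(S, L, L)) {
    S <- paste0(substr(S, L, L), substr(S, 1L, L - 1L))
    p <- p - 1L
  }
  if (L == 1L) {
    b <- S
    run <- run_count(seq, p, -1L, b) + run_count(seq, p + 1L, 1L, b)
    ch <- if (b %in% c("C", "T")) b else COMPLEMENT[[b]]
    return(paste0("1:Ins:", ch, ":", min(run, 5L)))
  }
  n <- copy_count(seq, p + 1L, 1L, S) + copy_count(seq, p, -1L, S)
  paste0(min(L, 5L), ":Ins:R:", min(n, 5L))
}

#' Classify small insertions and deletions into the 83 indel categories
#'
#' Implements the COSMIC-style ID83 scheme: indels are binned by insertion
#' vs deletion and length (1, 2, 3, 4, 5+); 1 bp events by the homopolymer
#' run length of the affected base (pyrimidine-folded to C/T channels);
#' longer events by the number of additional exact tandem copies of the
#' indel sequence in the flanking reference; deletions with no tandem copy
#' by the length of flanking microhomology. Indels are left-normalized
#' before counting so repeat-unit counts are unambiguous; repeat context
#' takes precedence over microhomology.
#'
#' @param variants Data frame with columns `chrom`, `pos`, `ref`, `alt`
#'   (VCF-style anchored indels).
#' @inheritParams classify_snv_96
#' @param max_len Longest indel accepted, in base pairs.
#' @return `variants` as a tibble with an added `id83` column.
#' @export
classify_indel_83 <- function(variants, genome, max_len = 100L) {
  genome <- as_genome(genome)
  variants <- as_tibble(variants)
  if (nrow(variants) == 0) return(mutate(variants, id83 = character(0)))
  labs <- vapply(seq_len(nrow(variants)), function(i) {
    seq <- genome[[variants$chrom[i]]]
    if (is.null(seq)) abort(paste0("chromosome absent from genome: ",
                                   variants$chrom[i]))
    id83_label_one(seq, variants$pos[i], toupper(variants$ref[i]),
                   toupper(variants$alt[i]), max_len)
  }, character(1))
  mutate(variants, id83 = labs)
}

#' Summarize structural variants into the four broad classes with lengths
#'
#' Maps `SV_DEL`/`SV_INS`/`SV_DUP`/`SV_INV` records to DEL/INS/DUP/INV.
#' Length is `sv_end - pos` for deletions, duplications and inversions; for
#' insertions it is taken from an `ins_len` column when present and left
#' missing for unresolved insertions.
#'
#' @param variants Data frame of SV records with columns `chrom`, `pos`,
#'   `var_class`, `sv_end` and optionally `clone_id`, `ins_len`.
#' @return Tibble with columns `clone_id` (if present), `chrom`, `pos`,
#'   `sv_class` and `sv_len`.
#' @export
classify_sv <- function(variants) {
  variants <- as_tibble(variants)
  map <- c(SV_DEL = "DEL", SV_INS = "INS", SV_DUP = "DUP", SV_INV = "INV")
  if (nrow(variants) == 0) {
    return(mutate(variants, sv_class = character(0), sv_len = numeric(0)))
  }
  unknown <- setdiff(unique(variants$var_class), names(map))
  if (length(unknown)) {
    abort(paste0("unknown SV type: ", paste(unknown, collapse = ", ")))
  }
  out <- mutate(variants, sv_class = unname(map[.data$var_class]))
  ins_len <- if ("ins_len" %in% names(out)) out$ins_len else NA_real_
  out <- mutate(out, sv_len = ifelse(.data$sv_class == "INS",
                                     ins_len,
                                     .data$sv_end - .data$pos))
  bad <- !is.na(out$sv_len) & out$sv_class != "INS" & out$sv_len < 1
  if (any(bad)) abort("SV with sv_end < pos + 1")
  out
}

#' Build a categories-by-clones count matrix
#'
#' Tallies classified mutations per clone under one of the three category
#' schemes. Every category of the scheme is present (zero-filled), in the
#' canonical catalog row order, so matrices line up with reference catalogs.
#'
#' @param classified Data frame with a `clone_id` column and the category
#'   column for the chosen scheme (`sbs6`, `sbs96` or `id83`).
#' @param scheme One of `"6"`, `"96"`, `"83"`.
#' @param clone_ids Optional clone ordering (clones with no mutations get
#'   all-zero columns).
#' @return Tibble with a `category` column followed by one integer column
#'   per clone; column sums equal per-clone mutation counts.
#' @export
build_count_matrix <- function(classified, scheme = c("96", "6", "83"),
                               clone_ids = NULL) {
  scheme <- match.arg(scheme)
  col <- switch(scheme, "6" = "sbs6", "96" = "sbs96", "83" = "id83")
  cats <- switch(scheme, "6" = sbs6_types(), "96" = sbs96_categories(),
                 "83" = id83_categories())
  classified <- as_tibble(classified)
  if (nrow(classified) > 0) {
    if (!col %in% names(classified)) {
      abort(paste0("column `", col, "` not found; classify first"))
    }
    bad <- setdiff(unique(classified[[col]]), cats)
    if (length(bad)) {
      abort(paste0("labels outside the ", scheme, "-category scheme: ",
                   paste(head(bad, 3), collapse = ", ")))
    }
  }
  if (is.null(clone_ids)) {
    clone_ids <- if (nrow(classified)) sort(unique(classified$clone_id)) else character(0)
  }
  out <- tibble(category = cats)
  for (cl in clone_ids) {
    labs <- classified[[col]][classified$clone_id == cl]
    out[[cl]] <- as.integer(table(factor(labs, levels = cats)))
  }
  attr(out, "scheme") <- scheme
  out
}

#' Convert a count-matrix tibble to a base matrix
#'
#' @param counts Tibble from [build_count_matrix()] or a catalog read with
#'   [read_signature_catalog()]: first column categories, remaining columns
#'   numeric.
#' @return Numeric matrix with category rownames.
#' @export
as_count_matrix <- function(counts) {
  counts <- as_tibble(counts)
  m <- as.matrix(counts[, -1, drop = FALSE])
  rownames(m) <- counts[[1]]
  storage.mode(m) <- "double"
  m
}

#' Collapse an SBS96 count matrix to the six substitution types
#'
#' @param counts96 Count-matrix tibble with SBS96 categories.
#' @return Count-matrix tibble with 6 rows.
#' @export
collapse_96_to_6 <- function(counts96) {
  counts96 <- as_tibble(counts96)
  sub <- sub("^.\\[(.>.)\\].$", "\\1", counts96$category)
  out <- counts96 |>
    mutate(category = factor(sub, levels = sbs6_types())) |>
    group_by(.data$category) |>
    summarise(across(where(is.numeric), sum), .groups = "drop") |>
    mutate(category = as.character(.data$category))
  attr(out, "scheme") <- "6"
  out
}
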