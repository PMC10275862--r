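# Constructive ID83 fixture: one exemplar indel per category, on a
# dedicated mini-chromosome whose structure guarantees the category by
# construction (an independent re-statement of the published convention:
# homopolymer length for 1 bp events, tandem copy counts for longer
# events, flanking microhomology for non-repeat deletions). Flanks are
# all-G so they can neither extend C/T homopolymers, match the C/A/T-only
# motifs, nor contribute microhomology (motifs never start or end in G).

id83_fixture <- function() {
  G <- function(n) strrep("G", n)
  motif <- function(L) substr("CATTAC", 1, L) # no G; starts C, never ends G
  seqs <- character(0)
  rows <- list()
  add <- function(category, seq, pos, ref, alt) {
    nm <- sprintf("fx%03d", length(seqs) + 1L)
    seqs[nm] <<- seq
    rows[[length(rows) + 1L]] <<- tibble::tibble(
      chrom = nm, pos = pos, ref = ref, alt = alt, expected = category)
  }

  for (b in c("C", "T")) {
    # 1 bp deletions: homopolymer length d + 1 (6 for the 5+ bin)
    for (d in 0:5) {
      n <- if (d == 5) 6L else d + 1L
      seq <- paste0(G(10), strrep(b, n), G(10))
      add(paste0("1:Del:", b, ":", d), seq,
          pos = 10L, ref = paste0("G", b), alt = "G")
    }
    # 1 bp insertions: existing homopolymer length d (5 for the 5+ bin)
    for (d in 0:5) {
      n <- if (d == 5) 5L else d
      seq <- paste0(G(10), strrep(b, n), G(10))
      add(paste0("1:Ins:", b, ":", d), seq,
          pos = 10L, ref = "G", alt = paste0("G", b))
    }
  }

  # longer deletions at tandem repeats: r additional copies of the motif
  for (L in 2:5) {
    M <- motif(L)
    for (r in 0:5) {
      seq <- paste0(G(10), strrep(M, r + 1L), G(10))
      add(paste0(L, ":Del:R:", r), seq,
          pos = 10L, ref = paste0("G", M), alt = "G")
    }
  }

  # longer insertions at repeats: n existing copies of the inserted motif
  for (L in 2:5) {
    M <- motif(L)
    for (n_cp in 0:5) {
      seq <- paste0(G(10), strrep(M, n_cp), G(10))
      add(paste0(L, ":Ins:R:", n_cp), seq,
          pos = 10L, ref = "G", alt = paste0("G", M))
    }
  }

  # microhomology deletions: deleted sequence D, right flank starts with
  # its first m bases followed by G (D never contains G, so the
  # microhomology is exactly m and no tandem copy exists)
  mh_cases <- list(c(2, 1), c(3, 1), c(3, 2), c(4, 1), c(4, 2), c(4, 3),
                   c(5, 1), c(5, 2), c(5, 3), c(5, 4), c(5, 5))
  for (cs in mh_cases) {
    Lb <- cs[1]
    m <- cs[2]
    L <- max(Lb, m + 1L) # 5+ bin with m = 5 needs a 6 bp deletion
    D <- motif(L)
    seq <- paste0(G(10), D, substr(D, 1, m), G(10))
    add(paste0(Lb, ":Del:M:", m), seq,
        pos = 10L, ref = paste0("G", D), alt = "G")
  }

  list(genome = seqs, variants = dplyr::bind_rows(rows))
}
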