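#' Read a reference genome FASTA into a named character vector
#'
#' Sequences are held as plain upper-case character strings keyed by
#' chromosome name (the first whitespace-delimited token of each FASTA
#' header), which keeps single-base context lookups cheap.
#'
#' @param path Path to an (uncompressed or gzipped) FASTA file.
#' @return Named character vector, one element per sequence.
#' @export
read_genome <- function(path) {
  if (!file.exists(path)) abort(paste0("FASTA not found: ", path))
  seqs <- Biostrings::readDNAStringSet(path)
  out <- toupper(as.character(seqs))
  names(out) <- sub("\\s.*$", "", names(seqs))
  out
}

#' Write a genome to FASTA
#'
#' @param genome Named character vector of sequences.
#' @param path Output path.
#' @param width Line width for wrapping.
#' @return `path`, invisibly.
#' @export
write_genome <- function(genome, path, width = 70L) {
  stopifnot(is.character(genome), !is.null(names(genome)))
  dss <- Biostrings::DNAStringSet(genome)
  Biostrings::writeXStringSet(dss, path, width = width)
  invisible(path)
}

# Coerce a genome argument (named character or DNAStringSet) to named character.
as_genome <- function(genome) {
  if (inherits(genome, "DNAStringSet")) {
    out <- toupper(as.character(genome))
    names(out) <- sub("\\s.*$", "", names(genome))
    return(out)
  }
  if (is.character(genome) && !is.null(names(genome))) return(toupper(genome))
  abort("`genome` must be a named character vector or a DNAStringSet")
}

# Single-chromosome base lookup; returns "" outside the contig.
genome_base <- function(seq, pos) {
  ifelse(pos >= 1L & pos <= nchar(seq), substr(seq, pos, pos), "")
}
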