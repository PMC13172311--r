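#' Read a genome FASTA into memory
#'
#' Loads all chromosomes of a FASTA file as a `DNAStringSet`. Sequence names
#' are truncated at the first whitespace, matching common aligner behavior.
#'
#' @param path Path to a (plain-text) FASTA file.
#' @return A [Biostrings::DNAStringSet] keyed by chromosome name.
#' @export
read_genome <- function(path) {
  if (!file.exists(path)) stop("genome FASTA not found: ", path)
  g <- Biostrings::readDNAStringSet(path)
  names(g) <- sub("\\s.*$", "", names(g))
  g
}

#' Fetch a genomic subsequence in transcription orientation
#'
#' Coordinates are 0-based half-open. On the minus strand the reverse
#' complement is returned, so the string always reads 5' to 3' in
#' transcription orientation.
#'
#' @param genome A `DNAStringSet` from [read_genome()].
#' @param chrom Chromosome name.
#' @param start,end 0-based half-open interval.
#' @param strand `"+"` or `"-"`.
#' @return Uppercase nucleotide string of length `end - start`.
#' @export
fetch_sequence <- function(genome, chrom, start, end, strand = "+") {
  if (!chrom %in% names(genome)) stop("unknown chromosome: ", chrom)
  len <- Biostrings::width(genome)[match(chrom, names(genome))]
  if (start < 0 || end > len || start > end)
    stop("interval [", start, ",", end, ") out of bounds for ", chrom,
         " (length ", len, ")")
  if (end == start) return("")
  s <- toupper(as.character(Biostrings::subseq(genome[[chrom]], start + 1L, end)))
  if (strand == "-")
    s <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
  if (grepl("[^ACGTN]", s))
    warning("non-ACGTN characters in fetched sequence at ", chrom, ":", start)
  s
}

# Vectorized convenience wrapper over fetch_sequence().
fetch_sequences <- function(genome, chrom, start, end, strand) {
  n <- length(start)
  chrom <- rep_len(chrom, n); strand <- rep_len(strand, n)
  vapply(seq_len(n), function(i)
    fetch_sequence(genome, chrom[i], start[i], end[i], strand[i]), character(1))
}
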