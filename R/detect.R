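# Detection of candidate recursive splice sites (RSSs): junctions whose
# donor side coincides exactly with an annotated exon 3' end and whose
# acceptor falls strictly inside the following intron, at a YAG|NN motif.
#
# rs_point convention: the 0-based boundary coordinate between the YAG
# acceptor and the regenerated donor, in transcription orientation. On the
# plus strand rs_point is the junction end; on the minus strand it is the
# junction start. The acceptor trinucleotide occupies the 3 nt immediately
# upstream of the boundary (transcription-wise) and the regenerated donor
# the 2 nt immediately downstream.

#' Find hybrid junctions compatible with recursive splicing
#'
#' Keeps junctions whose donor boundary equals a deduplicated intron's
#' upstream-exon 3' end and whose acceptor boundary lies in the intron
#' interior at least `min_margin` nt from both intron ends. Acceptors that
#' coincide with the 5' start of an annotated exon of the host gene are
#' excluded as ordinary alternative acceptors -- unless that exon lies
#' entirely inside the host intron, in which case it is a putative RS-exon
#' and the junction is retained. Junctions whose donor matches exon ends in
#' more than one gene are skipped (counted in the attached `counts`).
#'
#' @param junctions data.frame from [read_junctions()].
#' @param ann A `genome_annotation` with introns derived
#'   ([derive_introns()]).
#' @param min_margin Minimum distance (nt) of the acceptor boundary from
#'   either intron end. Default 20.
#' @return data.frame of hybrid junctions with host gene/intron fields and
#'   `rs_point`; attribute `counts` tabulates exclusions.
#' @export
find_hybrid_junctions <- function(junctions, ann, min_margin = 20) {
  if (is.null(ann$introns)) stop("annotation has no introns; run derive_introns()")
  j <- junctions
  j$.row <- seq_len(nrow(j))
  j$donor_3p <- ifelse(j$strand == "+", j$start, j$end)
  j$rs_point <- ifelse(j$strand == "+", j$end, j$start)

  m <- merge(j, ann$introns, by = c("chrom", "strand", "donor_3p"),
             suffixes = c("", ".intron"))
  counts <- c(n_input = nrow(j), n_no_donor_match = 0L, n_multi_gene = 0L,
              n_outside_margin = 0L, n_alt_acceptor = 0L, n_kept = 0L)
  counts["n_no_donor_match"] <- sum(!(j$.row %in% m$.row))

  empty <- function() {
    out <- data.frame(chrom = character(), strand = character(),
                      start = integer(), end = integer(),
                      unique_reads = integer(), max_overhang = integer(),
                      gene_id = character(), intron_start = integer(),
                      intron_end = integer(), tx_index = integer(),
                      donor_3p = integer(), rs_point = integer())
    attr(out, "counts") <- counts
    out
  }
  if (nrow(m) == 0) return(empty())

  # junctions whose donor is shared by several genes are ambiguous
  ngene <- tapply(m$gene_id, m$.row, function(g) length(unique(g)))
  multi <- as.integer(names(ngene)[ngene > 1])
  counts["n_multi_gene"] <- length(multi)
  m <- m[!(m$.row %in% multi), ]

  inside <- (m$rs_point - m$start.intron) >= min_margin &
            (m$end.intron - m$rs_point) >= min_margin
  m <- m[inside, ]

  # a junction can sit in several same-donor introns (alternative
  # downstream exons); keep the most specific (shortest) containing intron
  if (nrow(m)) {
    m <- m[order(m$.row, m$end.intron - m$start.intron), ]
    m <- m[!duplicated(m$.row), ]
  }
  counts["n_outside_margin"] <- sum(!(j$.row %in% c(m$.row, multi))) -
    counts[["n_no_donor_match"]]

  if (nrow(m) == 0) return(empty())

  # exclusion: acceptor at an annotated exon 5' start of the host gene,
  # unless that exon is fully contained in the host intron (RS-exon case)
  ex_by_gene <- split(ann$exons, ann$exons$gene_id)
  is_alt <- vapply(seq_len(nrow(m)), function(i) {
    ex <- ex_by_gene[[m$gene_id[i]]]
    if (is.null(ex)) return(FALSE)
    start5 <- if (m$strand[i] == "+") ex$start else ex$end
    hit <- start5 == m$rs_point[i]
    if (!any(hit)) return(FALSE)
    contained <- ex$start >= m$start.intron[i] & ex$end <= m$end.intron[i]
    any(hit & !contained)
  }, logical(1))
  counts["n_alt_acceptor"] <- sum(is_alt)
  m <- m[!is_alt, ]
  counts["n_kept"] <- nrow(m)

  out <- data.frame(chrom = m$chrom, strand = m$strand,
                    start = m$start, end = m$end,
                    unique_reads = m$unique_reads,
                    max_overhang = m$max_overhang,
                    gene_id = m$gene_id,
                    intron_start = m$start.intron,
                    intron_end = m$end.intron,
                    tx_index = m$tx_index,
                    donor_3p = m$donor_3p, rs_point = m$rs_point,
                    stringsAsFactors = FALSE)
  out <- out[order(out$chrom, out$rs_point, out$gene_id), ]
  rownames(out) <- NULL
  attr(out, "counts") <- counts
  out
}

#' Call the acceptor/donor motif at candidate RS points
#'
#' Extracts, in transcription orientation, the acceptor trinucleotide
#' (`motif3`, the 3 nt ending at the boundary) and the regenerated donor
#' dinucleotide (`donor2`, the 2 nt after the boundary). The motif passes
#' when `motif3` matches `[CT]AG` (Y-A-G); an N anywhere in the 5-nt window
#' fails with reason `"ambiguous_base"`.
#'
#' @param hybrids data.frame from [find_hybrid_junctions()] (or any frame
#'   with chrom, strand, rs_point).
#' @param genome `DNAStringSet` from [read_genome()].
#' @return Input with columns `motif3`, `donor2`, `motif_pass`,
#'   `motif_reason` added.
#' @export
call_motif <- function(hybrids, genome) {
  n <- nrow(hybrids)
  motif3 <- donor2 <- character(n)
  for (i in seq_len(n)) {
    p <- hybrids$rs_point[i]; ch <- hybrids$chrom[i]
    if (hybrids$strand[i] == "+") {
      motif3[i] <- fetch_sequence(genome, ch, p - 3L, p, "+")
      donor2[i] <- fetch_sequence(genome, ch, p, p + 2L, "+")
    } else {
      motif3[i] <- fetch_sequence(genome, ch, p, p + 3L, "-")
      donor2[i] <- fetch_sequence(genome, ch, p - 2L, p, "-")
    }
  }
  ambiguous <- grepl("N", motif3) | grepl("N", donor2)
  pass <- grepl("^[CT]AG$", motif3) & !ambiguous
  hybrids$motif3 <- motif3
  hybrids$donor2 <- donor2
  hybrids$motif_pass <- pass
  hybrids$motif_reason <- ifelse(ambiguous, "ambiguous_base",
                                 ifelse(pass, "", "not_yag"))
  hybrids
}

#' Match donor dinucleotides against an IUPAC-like pattern
#'
#' @param donor2 Character vector of 2-nt donor strings over A/C/G/T.
#' @param pattern 2-character pattern over A, C, G, T, N (any), V (A/C/G),
#'   Y (C/T), R (A/G).
#' @return Logical vector.
#' @export
classify_donor <- function(donor2, pattern) {
  sets <- list(A = "A", C = "C", G = "G", T = "T",
               N = c("A", "C", "G", "T"), V = c("A", "C", "G"),
               Y = c("C", "T"), R = c("A", "G"))
  letters2 <- strsplit(pattern, "")[[1]]
  if (length(letters2) != 2 || !all(letters2 %in% names(sets)))
    stop("invalid donor pattern: ", pattern)
  if (any(nchar(donor2) != 2 | grepl("[^ACGT]", donor2)))
    stop("donor2 strings must be 2 nt over A/C/G/T")
  substr(donor2, 1, 1) %in% sets[[letters2[1]]] &
    substr(donor2, 2, 2) %in% sets[[letters2[2]]]
}

#' Build a per-sample RSS candidate catalog
#'
#' Collapses hybrid junctions to one candidate per (gene, rs_point),
#' summing unique reads and taking the maximum overhang across
#' contributing records, ordered deterministically by (chrom, rs_point).
#' Motif-failing candidates are retained (flagged) for auditability.
#'
#' @param sample_id Sample identifier attached to the catalog.
#' @param hybrids Output of [call_motif()].
#' @return `rss_catalog` data.frame with one row per candidate and an
#'   `rss_id` of the form `gene:rs_point`.
#' @export
build_catalog <- function(sample_id, hybrids) {
  if (nrow(hybrids) == 0) {
    out <- cbind(data.frame(sample_id = character(), rss_id = character()),
                 hybrids)
    class(out) <- c("rss_catalog", "data.frame")
    attr(out, "sample_id") <- sample_id
    return(out)
  }
  key <- paste(hybrids$gene_id, hybrids$rs_point, sep = ":")
  reads <- tapply(hybrids$unique_reads, key, sum)
  over <- tapply(hybrids$max_overhang, key, max)
  first <- hybrids[!duplicated(key), ]
  fkey <- paste(first$gene_id, first$rs_point, sep = ":")
  first$unique_reads <- as.integer(reads[fkey])
  first$max_overhang <- as.integer(over[fkey])
  first$rss_id <- fkey
  first$sample_id <- sample_id
  out <- first[order(first$chrom, first$rs_point, first$gene_id), ]
  rownames(out) <- NULL
  class(out) <- c("rss_catalog", "data.frame")
  attr(out, "sample_id") <- sample_id
  out
}
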