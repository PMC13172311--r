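# Gene annotation handling. All internal coordinates are 0-based
# half-open; conversion from the 1-based inclusive GFF3 convention (and
# back) happens only at the file boundary. "Upstream", "downstream" and
# "exon 3' end" always refer to transcription orientation: on the plus
# strand an exon's 3' boundary is its (half-open) end coordinate, on the
# minus strand it is its start coordinate.

#' Read gene annotation from GFF3 or BED12
#'
#' GFF3 input must contain gene, mRNA/transcript and exon features linked
#' by ID/Parent attributes. BED12 input defines one transcript per line
#' (blocks are the exons); the BED name doubles as gene and transcript id.
#'
#' @param path Annotation file path.
#' @param format `"auto"` (by extension), `"gff3"` or `"bed12"`.
#' @return A `genome_annotation` list with data frames `genes`,
#'   `transcripts` and `exons` (0-based half-open coordinates); introns are
#'   added by [derive_introns()].
#' @export
read_annotation <- function(path, format = c("auto", "gff3", "bed12")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("annotation file not found: ", path)
  if (format == "auto")
    format <- if (grepl("\\.bed(\\.gz)?$", path, ignore.case = TRUE)) "bed12" else "gff3"
  ann <- switch(format,
                gff3 = read_annotation_gff3(path),
                bed12 = read_annotation_bed12(path))
  validate_annotation(ann)
  ann
}

read_annotation_gff3 <- function(path) {
  gr <- rtracklayer::import(path, format = "gff3")
  type <- as.character(S4Vectors::mcols(gr)$type)
  id <- S4Vectors::mcols(gr)$ID
  parent <- S4Vectors::mcols(gr)$Parent

  gi <- which(type == "gene")
  ti <- which(type %in% c("mRNA", "transcript"))
  ei <- which(type == "exon")
  if (!length(gi) || !length(ti) || !length(ei))
    stop("GFF3 must contain gene, mRNA/transcript and exon features: ", path)

  genes <- data.frame(
    gene_id = as.character(id[gi]),
    chrom = as.character(GenomicRanges::seqnames(gr)[gi]),
    strand = as.character(GenomicRanges::strand(gr)[gi]),
    start = GenomicRanges::start(gr)[gi] - 1L,
    end = GenomicRanges::end(gr)[gi],
    stringsAsFactors = FALSE)

  tx_parent <- vapply(parent[ti], function(p) {
    if (!length(p)) NA_character_ else p[[1]]
  }, character(1))
  transcripts <- data.frame(
    transcript_id = as.character(id[ti]),
    gene_id = tx_parent, stringsAsFactors = FALSE)
  if (anyNA(transcripts$gene_id))
    stop("transcript with no gene parent in ", path)

  exon_parents <- parent[ei]
  if (any(lengths(exon_parents) == 0))
    stop("exon with no parent transcript in ", path)
  reps <- lengths(exon_parents)
  exons <- data.frame(
    transcript_id = unlist(exon_parents, use.names = FALSE),
    chrom = rep(as.character(GenomicRanges::seqnames(gr)[ei]), reps),
    strand = rep(as.character(GenomicRanges::strand(gr)[ei]), reps),
    start = rep(GenomicRanges::start(gr)[ei] - 1L, reps),
    end = rep(GenomicRanges::end(gr)[ei], reps),
    stringsAsFactors = FALSE)
  exons$gene_id <- transcripts$gene_id[match(exons$transcript_id,
                                             transcripts$transcript_id)]
  if (anyNA(exons$gene_id))
    stop("exon parent not a known transcript in ", path)

  structure(list(genes = genes, transcripts = transcripts,
                 exons = exons, introns = NULL),
            class = "genome_annotation")
}

read_annotation_bed12 <- function(path) {
  gr <- rtracklayer::import(path, format = "bed")
  blocks <- S4Vectors::mcols(gr)$blocks
  if (is.null(blocks)) stop("BED input lacks block (exon) columns: ", path)
  name <- as.character(S4Vectors::mcols(gr)$name)
  chrom <- as.character(GenomicRanges::seqnames(gr))
  strand <- as.character(GenomicRanges::strand(gr))
  start0 <- GenomicRanges::start(gr) - 1L

  ex <- lapply(seq_along(gr), function(i) {
    b <- blocks[[i]]  # block ranges are 1-based relative to chromStart
    data.frame(transcript_id = name[i], chrom = chrom[i], strand = strand[i],
               start = start0[i] + GenomicRanges::start(b) - 1L,
               end = start0[i] + GenomicRanges::end(b),
               gene_id = name[i], stringsAsFactors = FALSE)
  })
  exons <- do.call(rbind, ex)
  genes <- data.frame(gene_id = name, chrom = chrom, strand = strand,
                      start = start0, end = GenomicRanges::end(gr),
                      stringsAsFactors = FALSE)
  transcripts <- data.frame(transcript_id = name, gene_id = name,
                            stringsAsFactors = FALSE)
  structure(list(genes = genes, transcripts = transcripts,
                 exons = exons, introns = NULL),
            class = "genome_annotation")
}

validate_annotation <- function(ann) {
  if (!all(ann$genes$strand %in% c("+", "-")))
    stop("gene strand must be '+' or '-'")
  ex <- ann$exons[order(ann$exons$transcript_id, ann$exons$start), ]
  for (tx in split(ex, ex$transcript_id)) {
    n <- nrow(tx)
    if (n < 2) next
    if (any(tx$start[-1] < tx$end[-n]))
      stop("overlapping exons within transcript ", tx$transcript_id[1])
    if (any(tx$start[-1] == tx$end[-n]))
      stop("zero-length intron (abutting exons) in transcript ",
           tx$transcript_id[1])
  }
  invisible(ann)
}

#' Derive introns from exon structure
#'
#' Introns are the gaps between consecutive exons of each transcript,
#' deduplicated per gene by (interval, upstream-exon 3' end) so that a
#' junction is matched once even when several isoforms share an intron.
#' Each intron carries its transcription-order index (reversed on the
#' minus strand) and the donor boundary `donor_3p` (the upstream exon's 3'
#' end: intron start on `+`, intron end on `-`).
#'
#' @param ann A `genome_annotation`.
#' @return The annotation with an `introns` data frame added.
#' @export
derive_introns <- function(ann) {
  ex <- ann$exons[order(ann$exons$transcript_id, ann$exons$start), ]
  parts <- lapply(split(ex, ex$transcript_id), function(tx) {
    n <- nrow(tx)
    if (n < 2) return(NULL)
    strand <- tx$strand[1]
    idx <- if (strand == "+") seq_len(n - 1) else rev(seq_len(n - 1))
    data.frame(gene_id = tx$gene_id[1], chrom = tx$chrom[1], strand = strand,
               start = tx$end[-n], end = tx$start[-1],
               tx_index = idx, stringsAsFactors = FALSE)
  })
  introns <- do.call(rbind, c(parts, list(make.row.names = FALSE)))
  if (is.null(introns)) {
    introns <- data.frame(gene_id = character(), chrom = character(),
                          strand = character(), start = integer(),
                          end = integer(), tx_index = integer())
  } else {
    key <- paste(introns$gene_id, introns$start, introns$end)
    introns <- introns[!duplicated(key), ]
  }
  introns$donor_3p <- ifelse(introns$strand == "+", introns$start, introns$end)
  introns <- introns[order(introns$chrom, introns$start, introns$end), ]
  rownames(introns) <- NULL
  ann$introns <- introns
  ann
}

#' Write annotation back to GFF3
#'
#' Inverse of [read_annotation()] for the GFF3 dialect: internal 0-based
#' half-open intervals are converted back to 1-based inclusive.
#'
#' @param ann A `genome_annotation`.
#' @param path Output path.
#' @export
write_annotation_gff3 <- function(ann, path) {
  mk <- function(df, type, id = NULL, parent = NULL) {
    gr <- GenomicRanges::GRanges(
      df$chrom, IRanges::IRanges(df$start + 1L, df$end), strand = df$strand)
    S4Vectors::mcols(gr)$type <- type
    S4Vectors::mcols(gr)$ID <- if (is.null(id)) NA_character_ else id
    S4Vectors::mcols(gr)$Parent <- if (is.null(parent))
      IRanges::CharacterList(rep(list(character(0)), nrow(df)))
    else IRanges::CharacterList(as.list(parent))
    gr
  }
  tx <- ann$transcripts
  txspan <- do.call(rbind, lapply(split(ann$exons, ann$exons$transcript_id),
    function(e) data.frame(transcript_id = e$transcript_id[1],
                           chrom = e$chrom[1], strand = e$strand[1],
                           start = min(e$start), end = max(e$end))))
  txspan <- txspan[match(tx$transcript_id, txspan$transcript_id), ]
  gr <- c(mk(ann$genes, "gene", id = ann$genes$gene_id),
          mk(txspan, "mRNA", id = tx$transcript_id, parent = tx$gene_id),
          mk(ann$exons, "exon", parent = ann$exons$transcript_id))
  rtracklayer::export(gr, path, format = "gff3")
  invisible(path)
}
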