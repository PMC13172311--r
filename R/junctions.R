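# Splice-junction table I/O (STAR SJ.out.tab dialect) and sample manifest.

#' Read a STAR-style splice junction table
#'
#' Expects the nine-column SJ.out.tab dialect: chrom, first intronic base
#' (1-based), last intronic base (1-based), strand code (0 undefined /
#' 1 `+` / 2 `-`), intron motif code, annotated flag, unique reads,
#' multimapping reads, max overhang. Intervals are converted to 0-based
#' half-open; multimapping reads are ignored (only uniquely mapped reads
#' enter the analysis).
#'
#' @param path Junction TSV path.
#' @param keep_undetermined Keep records with strand code 0 (as strand
#'   `"*"`)? Default drops them; the dropped count is attached as attribute
#'   `n_undetermined_dropped`.
#' @return data.frame with columns chrom, start, end (0-based half-open
#'   spliced-out interval), strand, unique_reads, max_overhang.
#' @export
read_junctions <- function(path, keep_undetermined = FALSE) {
  if (!file.exists(path)) stop("junction table not found: ", path)
  dt <- data.table::fread(path, header = FALSE, sep = "\t",
                          colClasses = "character", data.table = FALSE)
  if (ncol(dt) < 9)
    stop("junction table has ", ncol(dt), " columns; expected 9: ", path)
  ints <- lapply(c(2, 3, 4, 7, 9), function(k) {
    v <- suppressWarnings(as.integer(dt[[k]]))
    if (anyNA(v))
      stop("non-integer value in column ", k, " of ", path,
           " (first bad line: ", which(is.na(v))[1], ")")
    v
  })
  s1 <- ints[[1]]; e1 <- ints[[2]]; code <- ints[[3]]
  uniq <- ints[[4]]; over <- ints[[5]]
  if (any(s1 > e1)) stop("junction start > end in ", path)
  if (any(uniq < 0)) stop("negative unique read count in ", path)
  if (any(over < 0)) stop("negative overhang in ", path)
  strand <- c("*", "+", "-")[code + 1L]
  keep <- code != 0L | keep_undetermined
  out <- data.frame(chrom = dt[[1]][keep], start = s1[keep] - 1L,
                    end = e1[keep], strand = strand[keep],
                    unique_reads = uniq[keep], max_overhang = over[keep],
                    stringsAsFactors = FALSE)
  attr(out, "n_undetermined_dropped") <- sum(!keep)
  out
}

#' Write junction records in the SJ.out.tab dialect
#'
#' Inverse of [read_junctions()]; used by the synthetic data generator.
#'
#' @param junctions data.frame as returned by [read_junctions()].
#' @param path Output path.
#' @export
write_junctions_sj <- function(junctions, path) {
  code <- match(junctions$strand, c("*", "+", "-")) - 1L
  dt <- data.table::data.table(
    chrom = junctions$chrom, start = junctions$start + 1L,
    end = junctions$end, strand = code, motif = 0L, annotated = 0L,
    unique = junctions$unique_reads, multi = 0L,
    overhang = junctions$max_overhang)
  data.table::fwrite(dt, path, sep = "\t", col.names = FALSE)
  invisible(path)
}

#' Read a sample manifest
#'
#' Tab-separated with header columns sample_id, condition,
#' total_mapped_reads, library (`total` or `polyA`), junction_path,
#' coverage_path. Relative paths are resolved against the manifest's
#' directory.
#'
#' @param path Manifest TSV path.
#' @return Validated data.frame of samples.
#' @export
read_manifest <- function(path) {
  if (!file.exists(path)) stop("manifest not found: ", path)
  m <- utils::read.delim(path, stringsAsFactors = FALSE)
  req <- c("sample_id", "condition", "total_mapped_reads", "library",
           "junction_path", "coverage_path")
  missing <- setdiff(req, names(m))
  if (length(missing))
    stop("manifest lacks columns: ", paste(missing, collapse = ", "))
  if (anyDuplicated(m$sample_id))
    stop("duplicate sample_id in manifest: ", path)
  if (any(m$total_mapped_reads <= 0))
    stop("total_mapped_reads must be positive")
  if (!all(m$library %in% c("total", "polyA")))
    stop("library must be 'total' or 'polyA'")
  base <- dirname(path)
  fix <- function(p) ifelse(grepl("^/", p), p, file.path(base, p))
  m$junction_path <- fix(m$junction_path)
  m$coverage_path <- fix(m$coverage_path)
  m
}
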