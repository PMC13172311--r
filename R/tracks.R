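# Per-base signal tracks (RNA-seq coverage or PhastCons conservation).
# Values are stored run-length encoded per chromosome; positions absent
# from the source bedGraph read as 0, with a parallel presence mask so
# stored zeros can be told apart from missing data.

new_signal_track <- function(values, present, kind) {
  structure(list(values = values, present = present, kind = kind),
            class = "signal_track")
}

#' Read a bedGraph file as a per-base signal track
#'
#' bedGraph intervals are 0-based half-open; per-base values are
#' materialized as run-length encoded vectors. Overlapping intervals are an
#' error. Positions not covered by any interval read as 0.
#'
#' @param path Path to a bedGraph file.
#' @param kind `"coverage"` (values must be >= 0) or `"conservation"`
#'   (values must be in `[0, 1]`).
#' @return A `signal_track` object, queried with [track_values()] /
#'   [track_mean()].
#' @export
read_track <- function(path, kind = c("coverage", "conservation")) {
  kind <- match.arg(kind)
  if (!file.exists(path)) stop(kind, " bedGraph not found: ", path)
  gr <- rtracklayer::import(path, format = "bedGraph")
  score <- S4Vectors::mcols(gr)$score
  if (any(score < 0)) stop("negative values in ", kind, " track: ", path)
  if (kind == "conservation" && any(score > 1))
    stop("conservation values > 1 in track: ", path)
  cov1 <- GenomicRanges::coverage(gr)
  if (any(max(cov1) > 1))
    stop("overlapping intervals in bedGraph: ", path)
  vals <- GenomicRanges::coverage(gr, weight = "score")
  new_signal_track(as.list(vals), as.list(cov1 > 0L), kind)
}

#' Query per-base values from a signal track
#'
#' @param track A `signal_track`.
#' @param chrom Chromosome name.
#' @param start,end 0-based half-open interval.
#' @return Numeric vector of length `end - start`; unstored positions are 0.
#' @export
track_values <- function(track, chrom, start, end) {
  n <- end - start
  if (n < 0) stop("end < start in track query")
  v <- numeric(n)
  r <- track$values[[chrom]]
  if (is.null(r) || n == 0L) return(v)
  lo <- max(start, 0L) + 1L
  hi <- min(end, length(r))
  if (hi >= lo)
    v[(lo - start):(hi - start)] <- as.numeric(S4Vectors::window(r, lo, hi))
  v
}

#' Mean signal over an interval
#'
#' @inheritParams track_values
#' @return Mean of per-base values (0 for an empty interval).
#' @export
track_mean <- function(track, chrom, start, end) {
  if (end <= start) return(0)
  mean(track_values(track, chrom, start, end))
}

# Number of queried positions actually present in the source bedGraph.
track_present_count <- function(track, chrom, start, end) {
  r <- track$present[[chrom]]
  if (is.null(r)) return(0L)
  lo <- max(start, 0L) + 1L
  hi <- min(end, length(r))
  if (hi < lo) return(0L)
  sum(as.integer(S4Vectors::window(r, lo, hi)))
}

#' Write per-base values as a bedGraph file
#'
#' Zero runs are omitted (they read back as 0). Used by the synthetic data
#' generator to emit coverage and conservation tracks.
#'
#' @param values Named list: chromosome -> numeric per-base vector, where
#'   element `i` is the value at 0-based position `i - 1`.
#' @param path Output path.
#' @export
write_bedgraph <- function(values, path) {
  parts <- lapply(names(values), function(chrom) {
    v <- values[[chrom]]
    r <- rle(v)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths
    keep <- r$values != 0
    if (!any(keep)) return(NULL)
    data.table::data.table(chrom = chrom, start = starts[keep],
                           end = ends[keep], value = r$values[keep])
  })
  dt <- data.table::rbindlist(parts)
  data.table::fwrite(dt, path, sep = "\t", col.names = FALSE)
  invisible(path)
}
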