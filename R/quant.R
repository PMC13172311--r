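# Per-sample RS usage quantification, differential usage between
# conditions, and catalog-level metrics.

#' Compute RS usage for a set of RSSs in one sample
#'
#' Usage is the RS junction's unique reads divided by a denominator that
#' depends on `mode`: `"upstream_exon"` (default) sums unique reads over
#' all junctions sharing the RSS's upstream-exon donor (including the RS
#' junction itself, so usage is bounded by 1); `"flanking_exons"` uses the
#' reads of the canonical junction joining the two exons flanking the host
#' intron. Usage is `NA` (untestable) when the denominator is 0.
#'
#' @param rss data.frame of RSSs (needs rss_id, chrom, strand, rs_point,
#'   donor_3p, intron_start, intron_end), e.g. rows of an `rss_catalog`.
#' @param junctions Junction data.frame for the sample
#'   ([read_junctions()]).
#' @param mode Denominator definition (see above).
#' @return data.frame with rss_id, rs_reads, denom_reads, usage.
#' @export
compute_usage <- function(rss, junctions,
                          mode = c("upstream_exon", "flanking_exons")) {
  mode <- match.arg(mode)
  j <- junctions
  donor <- ifelse(j$strand == "+", j$start, j$end)
  donor_key <- paste(j$chrom, j$strand, donor)
  donor_tot <- tapply(j$unique_reads, donor_key, sum)
  jkey <- paste(j$chrom, j$strand, j$start, j$end)
  jreads <- tapply(j$unique_reads, jkey, sum)

  rs_start <- ifelse(rss$strand == "+", rss$donor_3p, rss$rs_point)
  rs_end <- ifelse(rss$strand == "+", rss$rs_point, rss$donor_3p)
  rs_key <- paste(rss$chrom, rss$strand, rs_start, rs_end)
  rs_reads <- as.numeric(jreads[rs_key])
  rs_reads[is.na(rs_reads)] <- 0

  denom <- if (mode == "upstream_exon") {
    d <- as.numeric(donor_tot[paste(rss$chrom, rss$strand, rss$donor_3p)])
    d[is.na(d)] <- 0
    d
  } else {
    ckey <- paste(rss$chrom, rss$strand, rss$intron_start, rss$intron_end)
    d <- as.numeric(jreads[ckey])
    d[is.na(d)] <- 0
    d
  }
  data.frame(rss_id = rss$rss_id, rs_reads = rs_reads, denom_reads = denom,
             usage = ifelse(denom > 0, rs_reads / denom, NA_real_),
             stringsAsFactors = FALSE)
}

# Pooled-variance two-sample two-tailed Student's t-test with a guard for
# constant data (t.test() refuses essentially-constant input).
student_t_pooled <- function(x, y) {
  nx <- length(x); ny <- length(y)
  sp2 <- (sum((x - mean(x))^2) + sum((y - mean(y))^2)) / (nx + ny - 2)
  if (sp2 <= 0) {
    d <- mean(x) - mean(y)
    if (d == 0) return(list(t = 0, p = 1))
    return(list(t = sign(d) * Inf, p = 0))
  }
  tt <- stats::t.test(x, y, var.equal = TRUE)
  list(t = unname(tt$statistic), p = tt$p.value)
}

#' Differential RS usage between two conditions
#'
#' Per RSS, compares usage between the reference and alternative condition
#' with a two-tailed pooled-variance Student's t-test (no multiple-testing
#' correction; a plain P cutoff is applied). A replicate's usage counts as
#' usable when the RS junction has reads, or -- for an RSS absent from that
#' replicate -- when its donor has at least `min_donor_reads` reads (the
#' absence is then informative, usage 0, rather than lack of power). RSSs
#' with fewer than two usable replicates in either condition are
#' untestable.
#'
#' @param usage Long data.frame with columns sample_id, rss_id, rs_reads,
#'   denom_reads, usage (rows of [compute_usage()] per sample).
#' @param manifest Sample manifest ([read_manifest()]).
#' @param condition_ref,condition_alt Condition labels to compare.
#' @param alpha P cutoff for gained/lost calls. Default 0.05.
#' @param min_donor_reads Donor coverage needed to treat a zero-read RSS
#'   as usage 0. Default 10.
#' @return data.frame with per-RSS means, t statistic, P-value and status
#'   in gained / lost / unchanged / untestable (gained: higher usage in
#'   `condition_alt`).
#' @export
differential_usage <- function(usage, manifest, condition_ref = "ctrl",
                               condition_alt = "ko", alpha = 0.05,
                               min_donor_reads = 10) {
  for (cond in c(condition_ref, condition_alt))
    if (!cond %in% manifest$condition)
      stop("condition missing from manifest: ", cond)
  usage$condition <- manifest$condition[match(usage$sample_id,
                                              manifest$sample_id)]
  if (anyNA(usage$condition))
    stop("usage table contains samples absent from the manifest")
  usage$usable <- !is.na(usage$usage) &
    (usage$rs_reads > 0 | usage$denom_reads >= min_donor_reads)

  res <- lapply(split(usage, usage$rss_id), function(u) {
    x <- u$usage[u$usable & u$condition == condition_ref]
    y <- u$usage[u$usable & u$condition == condition_alt]
    row <- data.frame(rss_id = u$rss_id[1], n_ref = length(x),
                      n_alt = length(y),
                      mean_ref = if (length(x)) mean(x) else NA_real_,
                      mean_alt = if (length(y)) mean(y) else NA_real_,
                      t_stat = NA_real_, p_value = NA_real_,
                      status = "untestable", stringsAsFactors = FALSE)
    if (length(x) >= 2 && length(y) >= 2) {
      tt <- student_t_pooled(x, y)
      row$t_stat <- tt$t; row$p_value <- tt$p
      row$status <- if (tt$p < alpha && mean(y) > mean(x)) "gained"
        else if (tt$p < alpha && mean(y) < mean(x)) "lost"
        else "unchanged"
    }
    row
  })
  out <- do.call(rbind, c(res, list(make.row.names = FALSE)))
  out[order(out$rss_id), , drop = FALSE]
}

#' RSSs per million mapped reads
#'
#' @param catalog An `rss_catalog` with `status` (pass rows are counted),
#'   or directly a numeric RSS count.
#' @param total_mapped_reads Total mapped reads of the sample.
#' @return Passing RSS count per million mapped reads.
#' @export
rss_per_million <- function(catalog, total_mapped_reads) {
  stopifnot(total_mapped_reads > 0)
  n <- if (is.data.frame(catalog)) sum(catalog$status == "pass")
       else as.numeric(catalog)
  n / (total_mapped_reads / 1e6)
}

#' Pearson correlation between RSS counts and median host-intron length
#'
#' @param counts Per-catalog total passing RSS counts (length >= 3).
#' @param median_lengths Per-catalog median length of introns hosting at
#'   least one passing RSS.
#' @return List with `rho` (NA when either variable has zero variance)
#'   and `n`.
#' @export
intron_length_correlation <- function(counts, median_lengths) {
  if (length(counts) != length(median_lengths))
    stop("counts and median_lengths differ in length")
  if (length(counts) < 3) stop("need at least 3 catalogs")
  rho <- if (stats::sd(counts) == 0 || stats::sd(median_lengths) == 0)
    NA_real_ else stats::cor(counts, median_lengths, method = "pearson")
  list(rho = rho, n = length(counts))
}

# Per-catalog summary used by intron_length_correlation(): passing RSS
# count and the median length of host introns with at least one pass.
catalog_summary <- function(catalog) {
  pass <- catalog[catalog$status == "pass", , drop = FALSE]
  hosts <- unique(pass[, c("gene_id", "intron_start", "intron_end")])
  list(n_pass = nrow(pass),
       median_intron_length = if (nrow(hosts))
         stats::median(hosts$intron_end - hosts$intron_start) else NA_real_)
}

#' Tabulate gained/lost RSSs and their RS-exon-less subsets
#'
#' @param diff Output of [differential_usage()].
#' @param links Output of [associate_rs_exon()] (rss_id, associated).
#' @return Named integer vector: gained, lost, gained_no_rs_exon,
#'   lost_no_rs_exon.
#' @export
gain_loss_summary <- function(diff, links) {
  assoc <- links$associated[match(diff$rss_id, links$rss_id)]
  assoc[is.na(assoc)] <- FALSE
  c(gained = sum(diff$status == "gained"),
    lost = sum(diff$status == "lost"),
    gained_no_rs_exon = sum(diff$status == "gained" & !assoc),
    lost_no_rs_exon = sum(diff$status == "lost" & !assoc))
}
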