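# Downstream annotation of RSS catalogs: RS-exon association,
# cryptic-exon coverage enrichment, conservation strata and profiles,
# position probability matrices, donor-class enrichment and
# alternative-splicing overlap enrichment.

#' Associate RSSs with annotated RS-exons
#'
#' An RS-exon is an annotated exon of the host gene that starts exactly at
#' the RS point (within `tolerance_nt`, transcription orientation) and
#' ends before the host intron's downstream exon, i.e. lies entirely
#' within the intron. RSSs without such an exon behave as "zero-length"
#' exons.
#'
#' @param rss data.frame of RSSs (rss_id, gene_id, chrom, strand,
#'   rs_point, intron_start, intron_end).
#' @param ann A `genome_annotation` including all isoforms (cryptic exons
#'   may be annotated on any isoform of the host gene).
#' @param tolerance_nt Allowed offset between exon start and rs_point.
#'   Default 0.
#' @return data.frame with rss_id, associated, exon_start, exon_end plus
#'   the input location fields.
#' @export
associate_rs_exon <- function(rss, ann, tolerance_nt = 0) {
  ex_by_gene <- split(ann$exons, ann$exons$gene_id)
  n <- nrow(rss)
  associated <- logical(n)
  exon_start <- exon_end <- rep(NA_integer_, n)
  for (i in seq_len(n)) {
    ex <- ex_by_gene[[rss$gene_id[i]]]
    if (is.null(ex)) next
    inside <- ex$start >= rss$intron_start[i] & ex$end <= rss$intron_end[i] &
      ex$end > ex$start
    start5 <- if (rss$strand[i] == "+") ex$start else ex$end
    hit <- which(inside & abs(start5 - rss$rs_point[i]) <= tolerance_nt)
    if (length(hit)) {
      hit <- hit[order(abs(start5[hit] - rss$rs_point[i]),
                       ex$end[hit] - ex$start[hit])][1]
      associated[i] <- TRUE
      exon_start[i] <- ex$start[hit]
      exon_end[i] <- ex$end[hit]
    }
  }
  data.frame(rss_id = rss$rss_id, gene_id = rss$gene_id, chrom = rss$chrom,
             strand = rss$strand, rs_point = rss$rs_point,
             intron_start = rss$intron_start, intron_end = rss$intron_end,
             associated = associated, exon_start = exon_start,
             exon_end = exon_end, stringsAsFactors = FALSE)
}

#' Flag cryptic exons by coverage enrichment
#'
#' An associated RS-exon is called cryptic when its mean RNA-seq coverage
#' exceeds `fold_threshold` times the mean over equal-width intronic
#' windows flanking it (both sides, truncated to the host intron;
#' pseudo-count `epsilon` on both means).
#'
#' @param links Output of [associate_rs_exon()]; all rows must be
#'   associated unless `skip_unassociated = TRUE` (unassociated rows then
#'   get NA).
#' @param coverage A coverage `signal_track`.
#' @param fold_threshold Strict fold cutoff. Default 2.
#' @param epsilon Pseudo-count. Default 0.5.
#' @param skip_unassociated Tolerate unassociated rows instead of erroring.
#' @return `links` with `coverage_fold` and `cryptic` columns.
#' @export
cryptic_exon_flag <- function(links, coverage, fold_threshold = 2,
                              epsilon = 0.5, skip_unassociated = FALSE) {
  if (any(!links$associated) && !skip_unassociated)
    stop("cryptic_exon_flag requires associated RS-exon links")
  n <- nrow(links)
  fold <- rep(NA_real_, n)
  for (i in which(links$associated)) {
    a <- links$exon_start[i]; b <- links$exon_end[i]
    w <- b - a
    ch <- links$chrom[i]
    exon_mean <- track_mean(coverage, ch, a, b)
    fl <- max(links$intron_start[i], a - w)
    fr <- min(links$intron_end[i], b + w)
    flank_vals <- c(track_values(coverage, ch, fl, a),
                    track_values(coverage, ch, b, fr))
    flank_mean <- if (length(flank_vals)) mean(flank_vals) else 0
    fold[i] <- (exon_mean + epsilon) / (flank_mean + epsilon)
  }
  links$coverage_fold <- fold
  links$cryptic <- !is.na(fold) & fold > fold_threshold
  links
}

#' Stratify RSSs by motif conservation
#'
#' High: mean motif PhastCons strictly above `threshold`; low otherwise.
#' Values exactly at the threshold go to "low" (the count of such boundary
#' cases is attached as attribute `n_boundary`).
#'
#' @param catalog Catalog with `conservation_mean`.
#' @param threshold Stratification cutoff. Default 0.45.
#' @return Catalog with factor column `cons_stratum`.
#' @export
stratify_conservation <- function(catalog, threshold = 0.45) {
  catalog$cons_stratum <- factor(
    ifelse(catalog$conservation_mean > threshold, "high", "low"),
    levels = c("high", "low"))
  attr(catalog, "n_boundary") <- sum(catalog$conservation_mean == threshold)
  catalog
}

#' Mean conservation profile around aligned sites
#'
#' Position 0 is the first base after the site boundary in transcription
#' orientation (the first regenerated-donor base for an RSS, the first
#' exonic base for a canonical acceptor); negative offsets are upstream.
#'
#' @param sites data.frame with chrom, strand, pos (0-based boundary
#'   coordinates); must be non-empty.
#' @param track A conservation (or any) `signal_track`.
#' @param half_window Window half-width. Default 15.
#' @return Numeric vector of per-offset means, length
#'   `2 * half_window + 1`, named by offset.
#' @export
conservation_profile <- function(sites, track, half_window = 15) {
  if (nrow(sites) == 0) stop("conservation_profile: empty site list")
  offs <- -half_window:half_window
  M <- matrix(0, nrow(sites), length(offs))
  for (i in seq_len(nrow(sites))) {
    p <- sites$pos[i]
    gpos <- if (sites$strand[i] == "+") p + offs else (p - 1L) - offs
    lo <- min(gpos)
    v <- track_values(track, sites$chrom[i], lo, max(gpos) + 1L)
    M[i, ] <- v[gpos - lo + 1L]
  }
  stats::setNames(colMeans(M), offs)
}

#' Draw random intronic control sites
#'
#' Samples positions uniformly from the given introns (respecting an edge
#' margin), for use as the random-control group of conservation profiles.
#'
#' @param introns data.frame with chrom, strand, start, end.
#' @param n Number of sites.
#' @param margin Minimum distance from intron ends. Default 20.
#' @param seed RNG seed.
#' @return data.frame with chrom, strand, pos.
#' @export
random_intronic_sites <- function(introns, n, margin = 20, seed = 1L) {
  ok <- introns[(introns$end - introns$start) > 2 * margin, , drop = FALSE]
  if (!nrow(ok)) stop("no introns wide enough for random sites")
  with_seed(seed, {
    idx <- sample.int(nrow(ok), n, replace = TRUE)
    pos <- ok$start[idx] + margin +
      vapply(ok$end[idx] - ok$start[idx] - 2 * margin,
             function(w) sample.int(w, 1L), integer(1))
    data.frame(chrom = ok$chrom[idx], strand = ok$strand[idx], pos = pos,
               stringsAsFactors = FALSE)
  })
}

#' Position probability matrix around aligned sites
#'
#' Column `j` gives P(A), P(C), P(G), P(T) at offset `j - half_window - 1`
#' from the site boundary (same alignment as [conservation_profile()]).
#' Ns are excluded from the column denominators; columns sum to 1.
#'
#' @param sites data.frame with chrom, strand, pos.
#' @param genome `DNAStringSet`.
#' @param half_window Window half-width. Default 10.
#' @return 4 x (2*half_window+1) matrix, rows A/C/G/T, columns named by
#'   offset.
#' @export
sequence_probability_matrix <- function(sites, genome, half_window = 10) {
  if (nrow(sites) == 0) stop("sequence_probability_matrix: empty site list")
  w <- 2L * half_window + 1L
  seqs <- vapply(seq_len(nrow(sites)), function(i) {
    p <- sites$pos[i]
    if (sites$strand[i] == "+")
      fetch_sequence(genome, sites$chrom[i], p - half_window,
                     p + half_window + 1L, "+")
    else
      fetch_sequence(genome, sites$chrom[i], p - 1L - half_window,
                     p + half_window, "-")
  }, character(1))
  mat <- matrix(0, 4, w, dimnames = list(c("A", "C", "G", "T"),
                                         -half_window:half_window))
  chars <- do.call(rbind, strsplit(seqs, ""))
  for (j in seq_len(w)) {
    col <- chars[, j]
    col <- col[col %in% rownames(mat)]
    if (!length(col)) stop("all-N column at offset ", j - half_window - 1L)
    tab <- table(factor(col, levels = rownames(mat)))
    mat[, j] <- as.numeric(tab) / sum(tab)
  }
  mat
}

#' Donor dinucleotide class enrichment among differential RSSs
#'
#' For each donor pattern and each direction (gained / lost), builds the
#' 2x2 table of pattern match vs non-match against direction vs unchanged
#' and applies a two-tailed Fisher's exact test. Patterns matching no RSS
#' at all report P = 1 and are flagged.
#'
#' @param diff Output of [differential_usage()] with a `donor2` column
#'   merged in.
#' @param patterns Donor patterns (see [classify_donor()]). Defaults to
#'   the mutually exclusive partition GT/GV/AT/AV/CN/TN plus the composite
#'   classes GN and AN.
#' @param directions Directions to test. Default gained and lost.
#' @return data.frame with the table cells, odds ratio, P and -log10(P).
#' @export
donor_class_enrichment <- function(diff,
                                   patterns = c("GT", "GV", "AT", "AV",
                                                "CN", "TN", "GN", "AN"),
                                   directions = c("gained", "lost")) {
  if (!"donor2" %in% names(diff))
    stop("diff must carry a donor2 column (merge from the catalog)")
  rows <- list()
  for (pat in patterns) {
    match_pat <- classify_donor(diff$donor2, pat)
    for (dir in directions) {
      in_dir <- diff$status == dir
      unch <- diff$status == "unchanged"
      a <- sum(in_dir & match_pat); b <- sum(in_dir & !match_pat)
      c_ <- sum(unch & match_pat); d <- sum(unch & !match_pat)
      flagged <- (a + c_) == 0
      if (flagged) {
        p <- 1; or_ <- NA_real_
      } else {
        ft <- stats::fisher.test(matrix(c(a, b, c_, d), 2, byrow = TRUE))
        p <- ft$p.value; or_ <- unname(ft$estimate)
      }
      rows[[length(rows) + 1L]] <- data.frame(
        label = pat, direction = dir, n_dir_match = a, n_dir_other = b,
        n_unch_match = c_, n_unch_other = d, odds_ratio = or_,
        p_value = p, neg_log10_p = -log10(p), flagged = flagged,
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, c(rows, list(make.row.names = FALSE)))
}

#' Overlap enrichment of RS genes with alternative-splicing event types
#'
#' Per AS type, a one-tailed (over-representation) hypergeometric P of the
#' overlap between RS-harboring genes and genes with that AS type, within
#' the given gene universe.
#'
#' @param rs_genes Character vector of genes harboring RSSs (must be a
#'   subset of `universe`).
#' @param as_events data.frame with columns gene_id, as_type (codes such
#'   as TE, TS, CE, IR, AA, AD, AF, AL).
#' @param universe Character vector of all genes tested for AS.
#' @return data.frame with per-type overlap counts, P and -log10(P).
#' @export
as_overlap_enrichment <- function(rs_genes, as_events, universe) {
  rs_genes <- unique(rs_genes)
  universe <- unique(universe)
  off <- setdiff(rs_genes, universe)
  if (length(off))
    stop("rs_genes not in universe: ", paste(utils::head(off, 5), collapse = ", "))
  N <- length(universe); k <- length(rs_genes)
  types <- sort(unique(as_events$as_type))
  rows <- lapply(types, function(ty) {
    tg <- intersect(unique(as_events$gene_id[as_events$as_type == ty]),
                    universe)
    m <- length(tg)
    x <- length(intersect(rs_genes, tg))
    p <- stats::phyper(x - 1, m, N - m, k, lower.tail = FALSE)
    data.frame(label = ty, n_overlap = x, n_type = m, n_rs = k,
               n_universe = N, p_value = p, neg_log10_p = -log10(p),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, c(rows, list(make.row.names = FALSE)))
}
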