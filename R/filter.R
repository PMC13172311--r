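# The three-criterion RSS filter: per-motif conservation, junction
# overhang support, and the sawtooth coverage criterion (fold change
# across the RS point plus a breakpoint permutation test), followed by
# poly(A)-library subtraction.

#' Filtering configuration
#'
#' Thresholds follow the published criteria: motif mean PhastCons strictly
#' greater than 0.5, junction overhang strictly greater than 5 nt, and a
#' sawtooth fold strictly greater than 2 with a breakpoint permutation
#' P below 0.01.
#'
#' @param cons_threshold Strict lower bound on the mean PhastCons over the
#'   5-nt YAG|NN motif. Default 0.5.
#' @param min_overhang Overhang must exceed this (strictly). Default 5.
#' @param fold_threshold Strict lower bound on the upstream/downstream
#'   coverage fold. Default 2.
#' @param perm_alpha Permutation P cutoff (strict). Default 0.01.
#' @param n_perm Number of permutation breakpoints. Default 1000.
#' @param window_nt Sawtooth window width (nt) on each side of the RS
#'   point, truncated to the intron. Default 500.
#' @param min_window_nt Minimum window width after truncation; shorter
#'   windows make the candidate untestable. Default 50.
#' @param epsilon Pseudo-count added to both window means in the fold
#'   statistic. Default 0.5.
#' @param min_margin Minimum distance of rs_point from intron ends at
#'   detection. Default 20.
#' @param min_polya_reads A candidate seen with at least this many reads in
#'   any poly(A) sample is subtracted. Default 1.
#' @param seed RNG seed for the permutation test (per-candidate substreams
#'   are derived from it, so results do not depend on candidate order).
#' @return A `filter_config` list.
#' @export
filter_config <- function(cons_threshold = 0.5, min_overhang = 5,
                          fold_threshold = 2, perm_alpha = 0.01,
                          n_perm = 1000, window_nt = 500, min_window_nt = 50,
                          epsilon = 0.5, min_margin = 20,
                          min_polya_reads = 1, seed = 1L) {
  stopifnot(cons_threshold > 0, min_overhang > 0, fold_threshold > 0,
            perm_alpha > 0, perm_alpha < 1, n_perm >= 1, window_nt > 0,
            min_window_nt > 0, epsilon > 0)
  structure(list(cons_threshold = cons_threshold, min_overhang = min_overhang,
                 fold_threshold = fold_threshold, perm_alpha = perm_alpha,
                 n_perm = as.integer(n_perm), window_nt = as.integer(window_nt),
                 min_window_nt = as.integer(min_window_nt), epsilon = epsilon,
                 min_margin = as.integer(min_margin),
                 min_polya_reads = min_polya_reads, seed = as.integer(seed)),
            class = "filter_config")
}

#' Conservation filter
#'
#' Scores each candidate by the arithmetic mean of per-base PhastCons
#' values over the 5 motif bases (YAG + NN, transcription orientation);
#' the candidate passes when the mean strictly exceeds the threshold.
#' Positions absent from the track contribute 0 and set a warning flag.
#'
#' @param catalog An `rss_catalog`.
#' @param cons A conservation `signal_track`.
#' @param cfg A [filter_config()].
#' @return Catalog with `conservation_mean`, `cons_pass`, `cons_warn`.
#' @export
conservation_filter <- function(catalog, cons, cfg = filter_config()) {
  n <- nrow(catalog)
  mean_score <- numeric(n); warn <- logical(n)
  for (i in seq_len(n)) {
    p <- catalog$rs_point[i]
    if (catalog$strand[i] == "+") { s <- p - 3L; e <- p + 2L }
    else { s <- p - 2L; e <- p + 3L }
    mean_score[i] <- track_mean(cons, catalog$chrom[i], s, e)
    warn[i] <- track_present_count(cons, catalog$chrom[i], s, e) < 5L
  }
  catalog$conservation_mean <- mean_score
  catalog$cons_pass <- mean_score > cfg$cons_threshold
  catalog$cons_warn <- warn
  catalog
}

#' Overhang filter
#'
#' Passes candidates whose junction max overhang strictly exceeds
#' `min_overhang` nt (i.e. at least 6 nt at the default).
#'
#' @inheritParams conservation_filter
#' @return Catalog with `overhang_pass`.
#' @export
overhang_filter <- function(catalog, cfg = filter_config()) {
  catalog$overhang_pass <- catalog$max_overhang > cfg$min_overhang
  catalog
}

# Sawtooth statistic and permutation test for one candidate.
# v: per-base intron coverage (genomic order), q: 0-based breakpoint
# offset within the intron, plus_strand: host gene orientation. mask:
# optional logical vector marking positions to exclude from window means
# (annotated intron-internal exons -- the criterion measures intronic
# signal density, so included cryptic-exon signal must not contaminate
# the windows). Returns up/down means, fold, permutation P.
sawtooth_one <- function(v, q, plus_strand, cfg, seed, mask = NULL) {
  L <- length(v)
  W <- cfg$window_nt; minW <- cfg$min_window_nt; eps <- cfg$epsilon
  left_w <- min(q, W); right_w <- min(L - q, W)
  if (min(left_w, right_w) < minW)
    return(list(untestable = TRUE, up_mean = NA_real_, down_mean = NA_real_,
                fold = NA_real_, p = NA_real_))
  keep <- if (is.null(mask)) rep(1, L) else as.numeric(!mask)
  cum <- c(0, cumsum(v * keep))
  cnt <- c(0, cumsum(keep))
  wmean <- function(a, b) {  # 0-based half-open window [a, b)
    n <- cnt[b + 1L] - cnt[a + 1L]
    ifelse(n > 0, (cum[b + 1L] - cum[a + 1L]) / n, 0)
  }
  stat <- function(qs) {
    lm <- wmean(pmax(qs - W, 0L), qs)
    rm_ <- wmean(qs, pmin(qs + W, L))
    if (plus_strand) (lm + eps) / (rm_ + eps) else (rm_ + eps) / (lm + eps)
  }
  S <- stat(q)
  lo <- minW; hi <- L - minW
  qs <- with_seed(seed, sample.int(hi - lo + 1L, cfg$n_perm, replace = TRUE) +
                    lo - 1L)
  Snull <- stat(qs)
  left_mean <- wmean(max(q - W, 0L), q)
  right_mean <- wmean(q, min(q + W, L))
  list(untestable = FALSE,
       up_mean = if (plus_strand) left_mean else right_mean,
       down_mean = if (plus_strand) right_mean else left_mean,
       fold = S,
       p = (1 + sum(Snull >= S)) / (cfg$n_perm + 1))
}

#' Sawtooth coverage test
#'
#' For each candidate, compares mean coverage in the `window_nt` window
#' upstream of the RS point (transcription orientation, truncated to the
#' intron) against the downstream window via the pseudo-counted fold
#' `(up + eps) / (down + eps)`, and evaluates its consistency with a
#' permutation null built by redrawing the breakpoint uniformly from the
#' intron interior (`n_perm` draws, seeded per candidate). The criterion
#' passes when the fold strictly exceeds `fold_threshold` and the add-one
#' permutation P is below `perm_alpha`. Candidates whose truncated windows
#' fall below `min_window_nt` are flagged untestable (a distinct failure
#' reason).
#'
#' Window means exclude positions covered by annotated exons of the host
#' gene lying inside the host intron (putative RS-exons) when an
#' annotation is supplied, so that included cryptic-exon signal cannot
#' contaminate the intronic density comparison.
#'
#' @param catalog An `rss_catalog` (needs intron bounds and rs_point).
#' @param coverage A coverage `signal_track` for the catalog's sample.
#' @param cfg A [filter_config()].
#' @param ann Optional `genome_annotation` used to mask intron-internal
#'   exons out of the windows.
#' @return Catalog with `sawtooth_up`, `sawtooth_down`, `sawtooth_fold`,
#'   `sawtooth_p`, `sawtooth_pass`, `sawtooth_untestable`.
#' @export
sawtooth_test <- function(catalog, coverage, cfg = filter_config(),
                          ann = NULL) {
  n <- nrow(catalog)
  up <- dn <- fold <- pv <- rep(NA_real_, n)
  untest <- logical(n)
  ex_by_gene <- if (!is.null(ann)) split(ann$exons, ann$exons$gene_id)
  for (i in seq_len(n)) {
    s <- catalog$intron_start[i]; e <- catalog$intron_end[i]
    v <- track_values(coverage, catalog$chrom[i], s, e)
    mask <- NULL
    if (!is.null(ann)) {
      ex <- ex_by_gene[[catalog$gene_id[i]]]
      ex <- ex[ex$start >= s & ex$end <= e, , drop = FALSE]
      if (!is.null(ex) && nrow(ex)) {
        mask <- logical(e - s)
        for (k in seq_len(nrow(ex)))
          mask[(ex$start[k] - s + 1L):(ex$end[k] - s)] <- TRUE
      }
    }
    res <- sawtooth_one(v, catalog$rs_point[i] - s,
                        catalog$strand[i] == "+", cfg,
                        derive_seed(cfg$seed, catalog$chrom[i],
                                    catalog$rs_point[i]), mask)
    up[i] <- res$up_mean; dn[i] <- res$down_mean
    fold[i] <- res$fold; pv[i] <- res$p; untest[i] <- res$untestable
  }
  catalog$sawtooth_up <- up
  catalog$sawtooth_down <- dn
  catalog$sawtooth_fold <- fold
  catalog$sawtooth_p <- pv
  catalog$sawtooth_untestable <- untest
  catalog$sawtooth_pass <- !untest & fold > cfg$fold_threshold &
    pv < cfg$perm_alpha
  catalog$sawtooth_pass[is.na(catalog$sawtooth_pass)] <- FALSE
  catalog
}

#' Poly(A)-library subtraction
#'
#' Flags candidates whose (gene, rs_point) was detected with at least
#' `min_polya_reads` unique reads in any poly(A)-enriched sample; RS
#' intermediates visible in mature poly(A) RNA are treated as artifacts.
#'
#' @param catalog An `rss_catalog`.
#' @param polya_catalogs List of pre-filter `rss_catalog`s from poly(A)
#'   samples.
#' @param cfg A [filter_config()].
#' @return Catalog with logical `in_polya`.
#' @export
polya_subtraction <- function(catalog, polya_catalogs, cfg = filter_config()) {
  seen <- character(0)
  for (pc in polya_catalogs)
    seen <- c(seen, pc$rss_id[pc$unique_reads >= cfg$min_polya_reads])
  catalog$in_polya <- catalog$rss_id %in% seen
  catalog
}

#' Apply the full filter chain to a candidate catalog
#'
#' Runs motif, conservation, overhang, sawtooth and poly(A) criteria and
#' assigns final status: `"pass"` requires all five. All evidence is
#' computed for every candidate (failing candidates are kept, flagged with
#' the first failing criterion), and per-stage survivor counts are attached
#' as attribute `stage_counts` (monotone non-increasing through the chain).
#'
#' @param catalog An `rss_catalog` from [build_catalog()].
#' @param cons Conservation `signal_track`.
#' @param coverage Coverage `signal_track` for this catalog's sample.
#' @param cfg A [filter_config()].
#' @param polya_catalogs List of poly(A)-sample catalogs (may be empty).
#' @param ann Optional annotation for RS-exon masking in the sawtooth
#'   windows (see [sawtooth_test()]).
#' @return Filtered catalog with `status` (`"pass"`/`"fail"`) and `flags`
#'   (first failing reason, or `"pass"`).
#' @export
apply_filters <- function(catalog, cons, coverage, cfg = filter_config(),
                          polya_catalogs = list(), ann = NULL) {
  catalog <- conservation_filter(catalog, cons, cfg)
  catalog <- overhang_filter(catalog, cfg)
  catalog <- sawtooth_test(catalog, coverage, cfg, ann)
  catalog <- polya_subtraction(catalog, polya_catalogs, cfg)

  m <- catalog$motif_pass
  c_ <- catalog$cons_pass
  o <- catalog$overhang_pass
  s <- catalog$sawtooth_pass
  p <- !catalog$in_polya
  pass <- m & c_ & o & s & p
  catalog$status <- ifelse(pass, "pass", "fail")
  catalog$flags <- ifelse(!m, ifelse(catalog$motif_reason == "ambiguous_base",
                                     "motif_ambiguous", "motif"),
                   ifelse(!c_, "conservation",
                   ifelse(!o, "overhang",
                   ifelse(!s, ifelse(catalog$sawtooth_untestable,
                                     "sawtooth_untestable", "sawtooth"),
                   ifelse(!p, "polya", "pass")))))
  attr(catalog, "stage_counts") <- c(
    candidates = nrow(catalog), motif = sum(m), conservation = sum(m & c_),
    overhang = sum(m & c_ & o), sawtooth = sum(m & c_ & o & s),
    polya = sum(pass))
  catalog
}

#' Permutation-test calibration on synthetic null introns
#'
#' Generates `n_sites` introns with flat Poisson coverage (no planted
#' step), runs the sawtooth permutation test at the intron midpoint of
#' each, and reports the fraction of nominal rejections. Used to verify
#' that the permutation P is well calibrated (the rejection rate at
#' `perm_alpha` should be close to `perm_alpha`).
#'
#' @param n_sites Number of null introns. Default 500.
#' @param intron_length Length (nt) of each simulated intron. Default 3000.
#' @param lambda Poisson mean of the flat coverage. Default 10.
#' @param cfg A [filter_config()].
#' @param seed RNG seed for coverage generation.
#' @return List with `fraction_significant`, `p_values`, `folds`.
#' @export
sawtooth_null_calibration <- function(n_sites = 500, intron_length = 3000,
                                      lambda = 10, cfg = filter_config(),
                                      seed = 1L) {
  pv <- folds <- numeric(n_sites)
  q <- as.integer(intron_length / 2)
  for (i in seq_len(n_sites)) {
    v <- with_seed(derive_seed(seed, "null_cov", i),
                   stats::rpois(intron_length, lambda))
    res <- sawtooth_one(v, q, plus_strand = TRUE, cfg,
                        derive_seed(seed, "null_perm", i))
    pv[i] <- res$p; folds[i] <- res$fold
  }
  list(fraction_significant = mean(pv < cfg$perm_alpha),
       p_values = pv, folds = folds)
}
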