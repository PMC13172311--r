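# End-to-end orchestration: detect -> filter -> quantify -> differential
# -> annotate -> report, over a sample manifest.

#' Run the full recursive-splicing pipeline
#'
#' Reads all inputs, detects RSS candidates per sample, applies the filter
#' chain (with poly(A) subtraction using the manifest's poly(A)-library
#' samples), quantifies usage of the union of passing RSSs in every
#' total-RNA sample, tests differential usage between the two conditions,
#' and computes the annotation statistics (RS-exon association, donor
#' class enrichment, conservation strata, per-sample RSS-per-million and
#' the intron-length correlation). Deterministic given `cfg$seed`.
#'
#' @param manifest_path Sample manifest TSV ([read_manifest()]).
#' @param genome_path Genome FASTA.
#' @param annotation_path GFF3 (or BED12) annotation.
#' @param conservation_path PhastCons-style bedGraph.
#' @param cfg A [filter_config()].
#' @param condition_ref,condition_alt Conditions compared by the
#'   differential test.
#' @param usage_mode Usage denominator, `"upstream_exon"` (default) or
#'   `"flanking_exons"`.
#' @param alpha Differential-usage P cutoff. Default 0.05.
#' @param min_donor_reads See [differential_usage()].
#' @param outdir Optional output directory for TSV reports.
#' @param quiet Suppress progress messages.
#' @return List with per-sample `catalogs`, the passing `rss_union`,
#'   the long `usage` table, `differential` results, RS-exon `links`,
#'   `gain_loss` counts, `donor_enrichment`, and `metrics`.
#' @export
run_pipeline <- function(manifest_path, genome_path, annotation_path,
                         conservation_path, cfg = filter_config(),
                         condition_ref = "ctrl", condition_alt = "ko",
                         usage_mode = "upstream_exon", alpha = 0.05,
                         min_donor_reads = 10, outdir = NULL,
                         quiet = FALSE) {
  say <- function(...) if (!quiet) message("[recsplice] ", ...)
  stage <- function(name, path) {
    if (!file.exists(path)) stop(name, " stage: input file not found: ", path)
  }
  stage("detect", manifest_path); stage("detect", genome_path)
  stage("detect", annotation_path); stage("filter", conservation_path)

  manifest <- read_manifest(manifest_path)
  genome <- read_genome(genome_path)
  ann <- derive_introns(read_annotation(annotation_path))
  cons <- read_track(conservation_path, "conservation")

  say("detect: ", nrow(manifest), " samples")
  junctions <- list(); catalogs <- list()
  for (i in seq_len(nrow(manifest))) {
    sid <- manifest$sample_id[i]
    stage("detect", manifest$junction_path[i])
    jx <- read_junctions(manifest$junction_path[i])
    junctions[[sid]] <- jx
    hy <- call_motif(find_hybrid_junctions(jx, ann, cfg$min_margin), genome)
    catalogs[[sid]] <- build_catalog(sid, hy)
  }

  total_ids <- manifest$sample_id[manifest$library == "total"]
  polya_ids <- manifest$sample_id[manifest$library == "polyA"]
  polya_cats <- catalogs[polya_ids]

  say("filter: ", length(total_ids), " total-RNA samples")
  filtered <- list()
  for (sid in total_ids) {
    cpath <- manifest$coverage_path[manifest$sample_id == sid]
    stage("filter", cpath)
    cov <- read_track(cpath, "coverage")
    filtered[[sid]] <- apply_filters(catalogs[[sid]], cons, cov, cfg,
                                     polya_cats, ann)
  }

  union_rows <- do.call(rbind, lapply(filtered, function(cat)
    cat[cat$status == "pass", , drop = FALSE]))
  rss_union <- if (is.null(union_rows) || nrow(union_rows) == 0) {
    filtered[[1]][0, , drop = FALSE]
  } else {
    u <- union_rows[!duplicated(union_rows$rss_id), , drop = FALSE]
    u[order(u$chrom, u$rs_point, u$gene_id), , drop = FALSE]
  }
  say("union of passing RSSs: ", nrow(rss_union))

  usage <- do.call(rbind, lapply(total_ids, function(sid) {
    u <- compute_usage(rss_union, junctions[[sid]], mode = usage_mode)
    u$sample_id <- sid
    u
  }))

  differential <- if (nrow(rss_union))
    differential_usage(usage, manifest, condition_ref, condition_alt,
                       alpha = alpha, min_donor_reads = min_donor_reads)
  else NULL
  if (!is.null(differential))
    differential$donor2 <- rss_union$donor2[match(differential$rss_id,
                                                  rss_union$rss_id)]

  links <- if (nrow(rss_union)) associate_rs_exon(rss_union, ann) else NULL
  gain_loss <- if (!is.null(differential) && !is.null(links))
    gain_loss_summary(differential, links)
  else c(gained = 0L, lost = 0L, gained_no_rs_exon = 0L, lost_no_rs_exon = 0L)

  donor_enr <- if (!is.null(differential) && nrow(differential))
    donor_class_enrichment(differential)
  else NULL

  strata <- if (nrow(rss_union)) stratify_conservation(rss_union) else NULL

  rpm <- vapply(total_ids, function(sid)
    rss_per_million(filtered[[sid]],
                    manifest$total_mapped_reads[manifest$sample_id == sid]),
    numeric(1))
  sums <- lapply(filtered, catalog_summary)
  ilc <- if (length(total_ids) >= 3)
    intron_length_correlation(
      vapply(sums, function(s) s$n_pass, numeric(1)),
      vapply(sums, function(s) s$median_intron_length %||% NA_real_,
             numeric(1)))
  else list(rho = NA_real_, n = length(total_ids))

  res <- list(manifest = manifest, catalogs = catalogs, filtered = filtered,
              rss_union = rss_union, usage = usage,
              differential = differential, links = links,
              gain_loss = gain_loss, donor_enrichment = donor_enr,
              strata = strata,
              metrics = list(rss_per_million = rpm,
                             intron_length_cor = ilc,
                             rs_exon_fraction = if (!is.null(links) &&
                                                    nrow(links))
                               mean(links$associated) else NA_real_),
              cfg = cfg)
  if (!is.null(outdir)) write_pipeline_outputs(res, outdir)
  res
}

# Write the standard TSV reports (header comments carry version, seed and
# key parameters; files are promoted atomically).
write_pipeline_outputs <- function(res, outdir) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  hdr <- output_header(seed = res$cfg$seed,
                       params = res$cfg[c("cons_threshold", "min_overhang",
                                          "fold_threshold", "perm_alpha",
                                          "n_perm", "window_nt")])
  for (sid in names(res$filtered))
    write_tsv_header(as.data.frame(res$filtered[[sid]]),
                     file.path(outdir, paste0("catalog_", sid, ".tsv")), hdr)
  write_tsv_header(as.data.frame(res$rss_union),
                   file.path(outdir, "rss_union.tsv"), hdr)
  write_tsv_header(res$usage, file.path(outdir, "usage.tsv"), hdr)
  if (!is.null(res$differential))
    write_tsv_header(res$differential,
                     file.path(outdir, "differential.tsv"), hdr)
  if (!is.null(res$links))
    write_tsv_header(res$links, file.path(outdir, "rs_exon_links.tsv"), hdr)
  if (!is.null(res$donor_enrichment))
    write_tsv_header(res$donor_enrichment,
                     file.path(outdir, "enrichment_donor.tsv"), hdr)
  summary_df <- data.frame(
    metric = c(paste0("rss_per_million_", names(res$metrics$rss_per_million)),
               "intron_length_cor_rho", "rs_exon_fraction",
               names(res$gain_loss)),
    value = c(unname(res$metrics$rss_per_million),
              res$metrics$intron_length_cor$rho,
              res$metrics$rs_exon_fraction, unname(res$gain_loss)))
  write_tsv_header(summary_df, file.path(outdir, "summary.tsv"), hdr)
  invisible(outdir)
}
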