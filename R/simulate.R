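# Ground-truthed synthetic data generator. Emits exactly the formats the
# I/O layer reads (FASTA, GFF3, bedGraph, STAR-style junction TSV,
# manifest TSV) plus a truth table, with the statistical structure the
# detection and filtering steps assume: YAG|NN motifs planted deep inside
# long introns, sawtooth intronic coverage modeled as multiplicative step
# drops on an exponential co-transcriptional decay, junction read counts
# binomially tied to planted usage, and decoy sites each failing exactly
# one filter criterion.

#' Simulation configuration
#'
#' Defaults define the standard synthetic experiment: 20 genes (2 long
#' introns each), 40 true RSSs (usage 0.25 in the reference condition; 20
#' of them dropping to 0.05 in the alternative condition, 20 unchanged),
#' 20 decoys (4 per failing criterion: motif, conservation, overhang,
#' sawtooth, poly(A)), a 4-fold coverage step at used RS points, 3
#' replicates per condition plus one poly(A) library, and replicate usage
#' noise of sd 0.03.
#'
#' @param n_genes Number of genes (strands alternate).
#' @param exons_per_gene Exons per canonical transcript.
#' @param exon_length Exon length (nt).
#' @param intron_length Length range (nt) introns are drawn from.
#'   Recursive splicing is a long-intron phenomenon; the default range
#'   also keeps the breakpoint permutation null well resolved relative to
#'   the 500-nt sawtooth windows.
#' @param intergenic Spacer between genes (nt).
#' @param n_rss_per_intron Maximum planted sites per intron.
#' @param n_rss_lost,n_rss_null,n_rss_gained True RSS counts by
#'   differential class (lost: high usage in `conditions[1]`, low in
#'   `conditions[2]`; null: equal; gained: the reverse).
#' @param n_decoy_motif,n_decoy_cons,n_decoy_overhang,n_decoy_sawtooth,n_decoy_polya
#'   Decoy counts, one failing criterion each.
#' @param donor_class_mix Probabilities over the mutually exclusive donor
#'   classes GT, GV, AT, AV, CN, TN (must sum to 1).
#' @param rs_exon_fraction Fraction of true RSSs given an annotated
#'   RS-exon isoform.
#' @param rs_exon_length RS-exon length range (nt).
#' @param cryptic_fraction Fraction of RS-exon-bearing sites whose exon
#'   gets a coverage boost (cryptic exons).
#' @param cryptic_boost Coverage multiplier over cryptic RS-exons.
#' @param usage_high,usage_low Planted usage means.
#' @param usage_sd Per-replicate Gaussian noise on usage.
#' @param step_fold Coverage fold drop at a fully used RS point.
#' @param base_coverage Intronic coverage at the intron 5' end.
#' @param exon_coverage_mult Exonic coverage multiplier.
#' @param decay_rate Exponential intronic decay per nt.
#' @param read_depth Poisson mean of per-intron donor junction reads.
#' @param replicates Replicates per condition (>= 2).
#' @param conditions Condition labels (reference first).
#' @param cons_motif_high,cons_motif_low,cons_sd Conservation means (and
#'   sd) for planted motifs; decoy_cons sites get the low mean.
#' @param total_mapped_reads Mapped-read total reported per sample.
#' @param polya_replicates Number of poly(A) samples.
#' @param site_margin Minimum distance of planted sites from intron ends.
#' @param site_spacing Minimum spacing between planted sites.
#' @param seed Master RNG seed.
#' @return A `simulation_config` list.
#' @export
simulation_config <- function(n_genes = 20, exons_per_gene = 4,
    exon_length = 150, intron_length = c(8000, 15000), intergenic = 500,
    n_rss_per_intron = 1,
    n_rss_lost = 20, n_rss_null = 20, n_rss_gained = 0,
    n_decoy_motif = 4, n_decoy_cons = 4, n_decoy_overhang = 4,
    n_decoy_sawtooth = 4, n_decoy_polya = 4,
    donor_class_mix = c(GT = 0.30, GV = 0.15, AT = 0.20, AV = 0.10,
                        CN = 0.15, TN = 0.10),
    rs_exon_fraction = 0.9, rs_exon_length = c(60, 120),
    cryptic_fraction = 0.2, cryptic_boost = 6,
    usage_high = 0.25, usage_low = 0.05, usage_sd = 0.03,
    step_fold = 4, base_coverage = 50, exon_coverage_mult = 3,
    decay_rate = 1e-4, read_depth = 200, replicates = 3,
    conditions = c("ctrl", "ko"),
    cons_motif_high = 0.85, cons_motif_low = 0.15, cons_sd = 0.05,
    total_mapped_reads = 5e7, polya_replicates = 1,
    site_margin = 600, site_spacing = 1300, seed = 20260901L) {
  stopifnot(abs(sum(donor_class_mix) - 1) < 1e-9,
            all(names(donor_class_mix) %in% c("GT", "GV", "AT", "AV",
                                              "CN", "TN")),
            usage_high > 0, usage_high < 1, usage_low >= 0, usage_low < 1,
            step_fold >= 1, replicates >= 2, length(conditions) == 2,
            intron_length[2] >= intron_length[1],
            intron_length[1] >= 2 * site_margin)
  cfg <- as.list(environment())
  cfg$seed <- as.integer(seed %% 2147483647)
  structure(cfg, class = "simulation_config")
}

# Draw a donor dinucleotide from a named class.
draw_donor <- function(class) {
  switch(class,
         GT = "GT",
         GV = sample(c("GA", "GC", "GG"), 1),
         AT = "AT",
         AV = sample(c("AA", "AC", "AG"), 1),
         CN = paste0("C", sample(c("A", "C", "G", "T"), 1)),
         TN = paste0("T", sample(c("A", "C", "G", "T"), 1)))
}

#' Simulate the genome, annotation and planted-site truth table
#'
#' Builds a random-sequence chromosome carrying `n_genes` multi-exon genes
#' on alternating strands, plants YAG|NN motifs (donors drawn from
#' `donor_class_mix`) at interior intron positions for every true and
#' decoy site, writes decoy-motif sites with a non-YAG (AAG) context, and
#' adds RS-exons as extra isoform exons for the configured fraction of
#' true sites. Fully deterministic given `cfg$seed`.
#'
#' @param cfg A [simulation_config()].
#' @return List with `genome` (DNAStringSet), `ann` (annotation with
#'   introns derived), `introns_canonical`, and `truth` (one row per
#'   planted site; `site_id` matches the catalog `rss_id` convention).
#' @export
simulate_genome <- function(cfg) {
  with_seed(cfg$seed, {
    chrom <- "chrS"
    epg <- cfg$exons_per_gene
    cursor <- 1000L
    exon_rows <- list(); gene_rows <- list(); tx_rows <- list()
    intron_rows <- list()
    for (g in seq_len(cfg$n_genes)) {
      gid <- sprintf("g%03d", g)
      strand <- if (g %% 2 == 1) "+" else "-"
      ilens <- as.integer(round(stats::runif(epg - 1, cfg$intron_length[1],
                                             cfg$intron_length[2])))
      starts <- integer(epg); ends <- integer(epg)
      pos <- cursor
      for (k in seq_len(epg)) {
        starts[k] <- pos; ends[k] <- pos + cfg$exon_length
        pos <- ends[k] + if (k < epg) ilens[k] else 0L
      }
      gene_rows[[g]] <- data.frame(gene_id = gid, chrom = chrom,
                                   strand = strand, start = starts[1],
                                   end = ends[epg])
      tid <- paste0(gid, ".t1")
      tx_rows[[g]] <- data.frame(transcript_id = tid, gene_id = gid)
      exon_rows[[g]] <- data.frame(transcript_id = tid, chrom = chrom,
                                   strand = strand, start = starts,
                                   end = ends, gene_id = gid)
      idx <- if (strand == "+") seq_len(epg - 1) else rev(seq_len(epg - 1))
      intron_rows[[g]] <- data.frame(gene_id = gid, chrom = chrom,
                                     strand = strand, start = ends[-epg],
                                     end = starts[-1], tx_index = idx)
      cursor <- ends[epg] + cfg$intergenic
    }
    genes <- do.call(rbind, gene_rows)
    transcripts <- do.call(rbind, tx_rows)
    exons <- do.call(rbind, exon_rows)
    introns <- do.call(rbind, intron_rows)
    genome_len <- cursor + 1000L
    chars <- sample(c("A", "C", "G", "T"), genome_len, replace = TRUE)

    # candidate slots: evenly spaced interior positions per intron,
    # capped at n_rss_per_intron sites per intron
    slots <- do.call(rbind, lapply(seq_len(nrow(introns)), function(i) {
      lo <- introns$start[i] + cfg$site_margin
      hi <- introns$end[i] - cfg$site_margin
      if (hi < lo) return(NULL)
      p <- seq(lo, hi, by = cfg$site_spacing)
      if (length(p) > cfg$n_rss_per_intron)
        p <- sort(sample(p, cfg$n_rss_per_intron))
      data.frame(intron = i, pos = as.integer(p))
    }))
    classes <- rep(c("true_lost", "true_null", "true_gained",
                     "decoy_motif", "decoy_cons", "decoy_overhang",
                     "decoy_sawtooth", "decoy_polya"),
                   c(cfg$n_rss_lost, cfg$n_rss_null, cfg$n_rss_gained,
                     cfg$n_decoy_motif, cfg$n_decoy_cons,
                     cfg$n_decoy_overhang, cfg$n_decoy_sawtooth,
                     cfg$n_decoy_polya))
    n_sites <- length(classes)
    if (n_sites > nrow(slots))
      stop("intron space too small for ", n_sites, " planted sites (",
           nrow(slots), " slots); widen intron_length or reduce sites")
    pick <- slots[sample.int(nrow(slots), n_sites), ]
    classes <- sample(classes)

    truth <- data.frame(
      site_id = character(n_sites), gene_id = character(n_sites),
      chrom = chrom, strand = character(n_sites),
      intron_start = integer(n_sites), intron_end = integer(n_sites),
      rs_point = pick$pos, donor_3p = integer(n_sites),
      motif3 = character(n_sites), donor2 = character(n_sites),
      donor_class = character(n_sites), class = classes,
      cons_class = character(n_sites),
      usage_ref = numeric(n_sites), usage_alt = numeric(n_sites),
      rs_exon = FALSE, rs_exon_start = NA_integer_,
      rs_exon_end = NA_integer_, cryptic = FALSE,
      stringsAsFactors = FALSE)

    extra_tx <- list(); extra_exons <- list()
    for (i in seq_len(n_sites)) {
      it <- introns[pick$intron[i], ]
      p <- pick$pos[i]
      strand <- it$strand
      cls <- classes[i]
      dclass <- sample(names(cfg$donor_class_mix), 1,
                       prob = cfg$donor_class_mix)
      d2 <- draw_donor(dclass)
      m3 <- paste0(if (cls == "decoy_motif") "A" else sample(c("C", "T"), 1),
                   "AG")
      # write motif into the sequence, strand-aware (chars is 1-based)
      if (strand == "+") {
        chars[(p - 2L):p] <- strsplit(m3, "")[[1]]
        chars[(p + 1L):(p + 2L)] <- strsplit(d2, "")[[1]]
      } else {
        chars[(p + 1L):(p + 3L)] <- strsplit(revcomp(m3), "")[[1]]
        chars[(p - 1L):p] <- strsplit(revcomp(d2), "")[[1]]
      }
      usage <- switch(cls,
        true_lost = c(cfg$usage_high, cfg$usage_low),
        true_gained = c(cfg$usage_low, cfg$usage_high),
        c(cfg$usage_high, cfg$usage_high))
      truth$gene_id[i] <- it$gene_id
      truth$strand[i] <- strand
      truth$intron_start[i] <- it$start
      truth$intron_end[i] <- it$end
      truth$donor_3p[i] <- if (strand == "+") it$start else it$end
      truth$motif3[i] <- m3
      truth$donor2[i] <- d2
      truth$donor_class[i] <- dclass
      truth$cons_class[i] <- if (cls == "decoy_cons") "low" else "high"
      truth$usage_ref[i] <- usage[1]
      truth$usage_alt[i] <- usage[2]
      truth$site_id[i] <- paste0(it$gene_id, ":", p)

      if (cls %in% c("true_lost", "true_null", "true_gained") &&
          stats::runif(1) < cfg$rs_exon_fraction) {
        elen <- as.integer(round(stats::runif(1, cfg$rs_exon_length[1],
                                              cfg$rs_exon_length[2])))
        ea <- if (strand == "+") p else p - elen
        eb <- if (strand == "+") p + elen else p
        truth$rs_exon[i] <- TRUE
        truth$rs_exon_start[i] <- ea
        truth$rs_exon_end[i] <- eb
        truth$cryptic[i] <- stats::runif(1) < cfg$cryptic_fraction
        tid <- sprintf("%s.rs%d", it$gene_id, i)
        extra_tx[[length(extra_tx) + 1L]] <-
          data.frame(transcript_id = tid, gene_id = it$gene_id)
        can <- exons[exons$gene_id == it$gene_id, ]
        iso <- rbind(can[, c("chrom", "strand", "start", "end")],
                     data.frame(chrom = chrom, strand = strand,
                                start = ea, end = eb))
        iso$transcript_id <- tid
        iso$gene_id <- it$gene_id
        extra_exons[[length(extra_exons) + 1L]] <- iso
      }
    }

    transcripts <- rbind(transcripts, do.call(rbind, extra_tx))
    exons <- rbind(exons, do.call(rbind, extra_exons))
    genome <- Biostrings::DNAStringSet(
      stats::setNames(paste(chars, collapse = ""), chrom))
    ann <- structure(list(genes = genes, transcripts = transcripts,
                          exons = exons[, c("transcript_id", "chrom",
                                            "strand", "start", "end",
                                            "gene_id")],
                          introns = NULL),
                     class = "genome_annotation")
    validate_annotation(ann)
    ann <- derive_introns(ann)
    list(genome = genome, ann = ann, introns_canonical = introns,
         truth = truth, cfg = cfg)
  })
}

# Planted usage of each truth site under a given condition label.
truth_usage <- function(truth, cfg, condition) {
  if (condition == cfg$conditions[1]) truth$usage_ref else truth$usage_alt
}

#' Simulate a per-sample coverage track
#'
#' Expected intronic coverage decays exponentially from the intron's
#' transcription 5' end and drops multiplicatively at each planted RS
#' point that carries a coverage step, by `step_fold^(usage / usage_high)`
#' for the sample's condition (a fully used site gives the full
#' `step_fold`; usage 0 gives no step). Cryptic RS-exons are boosted by
#' `cryptic_boost`. Per-base counts are Poisson draws around the expected
#' value. Poly(A) libraries have exonic signal only.
#'
#' @param sim Output of [simulate_genome()].
#' @param condition Condition label (ignored for poly(A)).
#' @param seed RNG seed for the Poisson draw.
#' @param library `"total"` or `"polyA"`.
#' @return Named list chrom -> per-base counts, ready for
#'   [write_bedgraph()].
#' @export
simulate_tracks <- function(sim, condition, seed, library = "total") {
  cfg <- sim$cfg
  L <- Biostrings::width(sim$genome)[1]
  expected <- numeric(L)
  can_ex <- sim$ann$exons[grepl("\\.t1$", sim$ann$exons$transcript_id), ]
  for (k in seq_len(nrow(can_ex)))
    expected[(can_ex$start[k] + 1L):can_ex$end[k]] <-
      cfg$base_coverage * cfg$exon_coverage_mult
  if (library == "total") {
    usage <- truth_usage(sim$truth, cfg, condition)
    for (k in seq_len(nrow(sim$introns_canonical))) {
      it <- sim$introns_canonical[k, ]
      len <- it$end - it$start
      d <- if (it$strand == "+") 0:(len - 1) else (len - 1):0
      expc <- cfg$base_coverage * exp(-cfg$decay_rate * d)
      in_it <- which(sim$truth$gene_id == it$gene_id &
                     sim$truth$intron_start == it$start &
                     sim$truth$intron_end == it$end &
                     sim$truth$class != "decoy_sawtooth")
      for (i in in_it) {
        u <- usage[i]
        drop <- cfg$step_fold^(-min(u / cfg$usage_high, 1))
        off <- sim$truth$rs_point[i] - it$start  # 0-based offset in intron
        idx <- if (it$strand == "+") (off + 1L):len else 1L:off
        expc[idx] <- expc[idx] * drop
      }
      cry <- which(sim$truth$gene_id == it$gene_id &
                   sim$truth$intron_start == it$start &
                   sim$truth$intron_end == it$end & sim$truth$cryptic)
      for (i in cry) {
        a <- sim$truth$rs_exon_start[i] - it$start
        b <- sim$truth$rs_exon_end[i] - it$start
        expc[(a + 1L):b] <- expc[(a + 1L):b] * cfg$cryptic_boost
      }
      expected[(it$start + 1L):it$end] <- expc
    }
  }
  counts <- with_seed(seed, stats::rpois(L, expected))
  stats::setNames(list(counts), names(sim$genome)[1])
}

#' Simulate the conservation track
#'
#' Writes clipped-normal PhastCons-like scores over every planted 5-nt
#' motif (high mean for conserved sites, low for conservation decoys),
#' conserved windows around canonical 3' acceptor sites, and sparse
#' low-value background patches elsewhere; all other positions are absent
#' (read as 0).
#'
#' @param sim Output of [simulate_genome()].
#' @param seed RNG seed.
#' @return Named list chrom -> per-base values for [write_bedgraph()].
#' @export
simulate_conservation <- function(sim, seed) {
  cfg <- sim$cfg
  L <- Biostrings::width(sim$genome)[1]
  clip01 <- function(x) pmin(pmax(x, 0), 1)
  with_seed(seed, {
    v <- numeric(L)
    n_patch <- max(1L, as.integer(L / 1000))
    pstart <- sample.int(L - 60L, n_patch)
    for (s in pstart) v[s:(s + 49L)] <- stats::runif(1, 0, 0.3)
    # canonical acceptors: transcription 3' end of each canonical intron
    for (k in seq_len(nrow(sim$introns_canonical))) {
      it <- sim$introns_canonical[k, ]
      bnd <- if (it$strand == "+") it$end else it$start
      win <- (bnd - 15L):(bnd + 15L)
      v[win + 1L] <- clip01(stats::rnorm(length(win), 0.55, 0.1))
      acc <- if (it$strand == "+") (it$end - 2L):it$end
             else (it$start + 1L):(it$start + 3L)
      v[acc] <- clip01(stats::rnorm(3, 0.85, 0.05))
    }
    for (i in seq_len(nrow(sim$truth))) {
      p <- sim$truth$rs_point[i]
      idx <- if (sim$truth$strand[i] == "+") (p - 2L):(p + 2L)
             else (p - 1L):(p + 3L)
      mu <- if (sim$truth$cons_class[i] == "high") cfg$cons_motif_high
            else cfg$cons_motif_low
      v[idx] <- clip01(stats::rnorm(5, mu, cfg$cons_sd))
    }
    stats::setNames(list(v), names(sim$genome)[1])
  })
}

#' Simulate a per-sample junction table
#'
#' Per canonical intron, total donor reads are Poisson(`read_depth`);
#' each planted site receives Binomial(total, usage + noise) reads and
#' the remainder goes to the canonical junction. Overhangs are >= 6 nt
#' except for overhang decoys (<= 5 nt). Poly(A) libraries contain
#' canonical junctions plus only the poly(A)-decoy RS junctions.
#'
#' @param sim Output of [simulate_genome()].
#' @param condition Condition label (poly(A) libraries use the reference
#'   usage).
#' @param seed RNG seed.
#' @param library `"total"` or `"polyA"`.
#' @return Junction data.frame in the [read_junctions()] layout.
#' @export
simulate_junctions <- function(sim, condition, seed, library = "total") {
  cfg <- sim$cfg
  usage <- if (library == "polyA") sim$truth$usage_ref
           else truth_usage(sim$truth, cfg, condition)
  with_seed(seed, {
    rows <- list()
    for (k in seq_len(nrow(sim$introns_canonical))) {
      it <- sim$introns_canonical[k, ]
      total <- stats::rpois(1, cfg$read_depth)
      in_it <- which(sim$truth$gene_id == it$gene_id &
                     sim$truth$intron_start == it$start &
                     sim$truth$intron_end == it$end)
      if (library == "polyA")
        in_it <- in_it[sim$truth$class[in_it] == "decoy_polya"]
      rs_reads <- integer(length(in_it))
      for (j in seq_along(in_it)) {
        i <- in_it[j]
        p_use <- min(max(usage[i] + stats::rnorm(1, 0, cfg$usage_sd), 0), 1)
        rs_reads[j] <- stats::rbinom(1, total, p_use)
      }
      canonical <- max(total - sum(rs_reads), 0L)
      rows[[length(rows) + 1L]] <- data.frame(
        chrom = it$chrom, start = it$start, end = it$end,
        strand = it$strand, unique_reads = canonical,
        max_overhang = sample(20:40, 1), stringsAsFactors = FALSE)
      for (j in seq_along(in_it)) {
        if (rs_reads[j] == 0) next
        i <- in_it[j]
        p <- sim$truth$rs_point[i]
        js <- if (it$strand == "+") it$start else p
        je <- if (it$strand == "+") p else it$end
        over <- if (sim$truth$class[i] == "decoy_overhang") sample(3:5, 1)
                else sample(10:40, 1)
        rows[[length(rows) + 1L]] <- data.frame(
          chrom = it$chrom, start = js, end = je, strand = it$strand,
          unique_reads = rs_reads[j], max_overhang = over,
          stringsAsFactors = FALSE)
      }
    }
    do.call(rbind, rows)
  })
}

#' Simulate and write a complete experiment directory
#'
#' Writes genome FASTA, GFF3 annotation, conservation bedGraph, one
#' junction table and one coverage bedGraph per sample (replicates per
#' condition plus poly(A) libraries), the sample manifest and the truth
#' table. Byte-deterministic given the configuration seed.
#'
#' @param cfg A [simulation_config()].
#' @param outdir Output directory (created if needed).
#' @return List with `dir`, file `paths`, the `truth` table, the read-back
#'   `manifest`, and the `sim` object.
#' @export
simulate_experiment <- function(cfg, outdir) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  dir.create(file.path(outdir, "junctions"), showWarnings = FALSE)
  dir.create(file.path(outdir, "coverage"), showWarnings = FALSE)
  sim <- simulate_genome(cfg)

  genome_path <- file.path(outdir, "genome.fa")
  Biostrings::writeXStringSet(sim$genome, genome_path)
  ann_path <- file.path(outdir, "annotation.gff3")
  write_annotation_gff3(sim$ann, ann_path)
  cons_path <- file.path(outdir, "conservation.bedGraph")
  write_bedgraph(simulate_conservation(sim, derive_seed(cfg$seed, "cons")),
                 cons_path)

  samples <- rbind(
    expand.grid(condition = cfg$conditions, rep = seq_len(cfg$replicates),
                library = "total", stringsAsFactors = FALSE),
    if (cfg$polya_replicates > 0)
      expand.grid(condition = "polyA", rep = seq_len(cfg$polya_replicates),
                  library = "polyA", stringsAsFactors = FALSE))
  samples$sample_id <- paste0(samples$condition, "_rep", samples$rep)

  man <- list()
  for (i in seq_len(nrow(samples))) {
    sid <- samples$sample_id[i]
    jx <- simulate_junctions(sim, samples$condition[i],
                             derive_seed(cfg$seed, sid, "junc"),
                             library = samples$library[i])
    jpath <- file.path("junctions", paste0(sid, ".sj.tab"))
    write_junctions_sj(jx, file.path(outdir, jpath))
    cov <- simulate_tracks(sim, samples$condition[i],
                           derive_seed(cfg$seed, sid, "cov"),
                           library = samples$library[i])
    cpath <- file.path("coverage", paste0(sid, ".bedGraph"))
    write_bedgraph(cov, file.path(outdir, cpath))
    man[[i]] <- data.frame(sample_id = sid, condition = samples$condition[i],
                           total_mapped_reads = cfg$total_mapped_reads,
                           library = samples$library[i],
                           junction_path = jpath, coverage_path = cpath,
                           stringsAsFactors = FALSE)
  }
  manifest_path <- file.path(outdir, "manifest.tsv")
  utils::write.table(do.call(rbind, man), manifest_path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  truth_path <- file.path(outdir, "truth.tsv")
  utils::write.table(sim$truth, truth_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  list(dir = outdir,
       paths = list(genome = genome_path, annotation = ann_path,
                    conservation = cons_path, manifest = manifest_path,
                    truth = truth_path),
       truth = sim$truth, manifest = read_manifest(manifest_path),
       sim = sim)
}

#' Score a detected RSS set against the planted truth
#'
#' @param pass_ids Character vector of passing `rss_id`s (union over
#'   samples), or a catalog data.frame with `rss_id` and `status`.
#' @param truth Truth table from [simulate_experiment()].
#' @return List with recall, precision, counts, and per-class
#'   false-positive breakdown.
#' @export
evaluate_against_truth <- function(pass_ids, truth) {
  if (is.data.frame(pass_ids))
    pass_ids <- pass_ids$rss_id[pass_ids$status == "pass"]
  pass_ids <- unique(pass_ids)
  true_ids <- truth$site_id[truth$class %in%
                            c("true_lost", "true_null", "true_gained")]
  tp <- intersect(pass_ids, true_ids)
  fp <- setdiff(pass_ids, true_ids)
  fp_class <- table(truth$class[match(intersect(fp, truth$site_id),
                                      truth$site_id)])
  list(recall = length(tp) / length(true_ids),
       precision = if (length(pass_ids)) length(tp) / length(pass_ids)
                   else NA_real_,
       n_true = length(true_ids), n_detected = length(pass_ids),
       n_tp = length(tp), n_fp = length(fp),
       fp_by_class = fp_class)
}
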