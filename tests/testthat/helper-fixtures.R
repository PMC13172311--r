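# Programmatic fixtures: tiny genomes, annotations, tracks and junction
# tables built in code and written to tempdir() as the plain-text formats
# the package reads.

# Build a genome_annotation directly from an exon table (0-based
# half-open, like the package's internal representation).
make_ann <- function(exons, gene_strand = NULL) {
  exons <- as.data.frame(exons, stringsAsFactors = FALSE)
  genes <- do.call(rbind, lapply(split(exons, exons$gene_id), function(e)
    data.frame(gene_id = e$gene_id[1], chrom = e$chrom[1],
               strand = e$strand[1], start = min(e$start), end = max(e$end),
               stringsAsFactors = FALSE)))
  transcripts <- unique(exons[, c("transcript_id", "gene_id")])
  structure(list(genes = genes, transcripts = transcripts,
                 exons = exons, introns = NULL),
            class = "genome_annotation")
}

exon_row <- function(tid, gid, chrom, strand, start, end) {
  data.frame(transcript_id = tid, gene_id = gid, chrom = chrom,
             strand = strand, start = start, end = end,
             stringsAsFactors = FALSE)
}

# Write a FASTA for named character sequences and read it back.
make_genome <- function(seqs) {
  path <- tempfile(fileext = ".fa")
  writeLines(unlist(lapply(names(seqs), function(n)
    c(paste0(">", n), seqs[[n]]))), path)
  recsplice::read_genome(path)
}

# Write a bedGraph from (chrom, start, end, value) rows and load it.
make_track <- function(rows, kind = "coverage") {
  path <- tempfile(fileext = ".bedGraph")
  write.table(rows, path, sep = "\t", quote = FALSE, col.names = FALSE,
              row.names = FALSE)
  recsplice::read_track(path, kind)
}

# Junction data.frame in the package's internal layout.
jrow <- function(chrom, start, end, strand, reads = 10, overhang = 20) {
  data.frame(chrom = chrom, start = start, end = end, strand = strand,
             unique_reads = reads, max_overhang = overhang,
             stringsAsFactors = FALSE)
}

# A deterministic random-sequence fixture of multi-exon genes on both
# strands, with junctions planted from each intron's donor to EVERY
# interior position (margin `margin`), for the detection-oracle check.
make_oracle_fixture <- function(n_genes = 10, intron_len = 400,
                                exon_len = 60, margin = 3, seed = 424242) {
  set.seed(seed)
  cursor <- 100L
  exons <- NULL
  for (g in seq_len(n_genes)) {
    gid <- sprintf("og%02d", g)
    strand <- if (g %% 2 == 1) "+" else "-"
    s1 <- cursor; e1 <- s1 + exon_len
    s2 <- e1 + intron_len; e2 <- s2 + exon_len
    s3 <- e2 + intron_len; e3 <- s3 + exon_len
    exons <- rbind(exons,
                   exon_row(paste0(gid, ".t1"), gid, "chrO", strand,
                            c(s1, s2, s3), c(e1, e2, e3)))
    cursor <- e3 + 150L
  }
  seq <- paste(sample(c("A", "C", "G", "T"), cursor + 200L, replace = TRUE),
               collapse = "")
  genome <- make_genome(list(chrO = seq))
  ann <- recsplice::derive_introns(make_ann(exons))
  introns <- ann$introns
  jx <- do.call(rbind, lapply(seq_len(nrow(introns)), function(i) {
    it <- introns[i, ]
    pts <- (it$start + margin):(it$end - margin)
    if (it$strand == "+") jrow("chrO", it$start, pts, "+")
    else jrow("chrO", pts, it$end, "-")
  }))
  list(genome = genome, ann = ann, junctions = jx, margin = margin)
}

# Session-cached experiments so expensive simulations run once per suite.
.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, builder) {
  if (!exists(key, envir = .fixture_cache))
    assign(key, builder(), envir = .fixture_cache)
  get(key, envir = .fixture_cache)
}

# Small, fast experiment for pipeline-level tests.
small_experiment <- function() {
  cached("small_exp", function() {
    cfg <- recsplice::simulation_config(
      n_genes = 9, exons_per_gene = 3, intron_length = c(6000, 8000),
      n_rss_lost = 6, n_rss_null = 6, n_decoy_motif = 1, n_decoy_cons = 1,
      n_decoy_overhang = 1, n_decoy_sawtooth = 1, n_decoy_polya = 1,
      replicates = 2, seed = 515151)
    recsplice::simulate_experiment(cfg, file.path(tempdir(), "small_exp"))
  })
}

small_pipeline_result <- function() {
  cached("small_res", function() {
    exp <- small_experiment()
    recsplice::run_pipeline(exp$paths$manifest, exp$paths$genome,
                            exp$paths$annotation, exp$paths$conservation,
                            cfg = recsplice::filter_config(seed = 99),
                            quiet = TRUE)
  })
}

# The default synthetic experiment (the study conditions) used by the
# end-to-end recovery check.
default_experiment <- function() {
  cached("default_exp", function() {
    recsplice::simulate_experiment(recsplice::simulation_config(),
                                   file.path(tempdir(), "default_exp"))
  })
}
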