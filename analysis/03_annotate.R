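#!/usr/bin/env Rscript
# Step 3 -- annotation statistics around the detected RSSs.
#
# Computes conservation profiles around canonical acceptors, detected
# RSSs and random intronic controls; the sequence probability matrix
# around RS points; cryptic-exon coverage enrichment over RS-exons;
# donor-class Fisher enrichment among differentially used sites; and
# AS-type overlap enrichment against a synthetic gene->AS-event table
# (RS genes enriched for core-exon events, mirroring the kind of input a
# splicing caller would provide).

library(recsplice)

union_path <- "results/pipeline/rss_union.tsv"
if (!file.exists(union_path)) stop("run analysis/02_run_pipeline.R first")
rss <- read.delim(union_path, comment.char = "#")
diff <- read.delim("results/pipeline/differential.tsv", comment.char = "#")
links <- read.delim("results/pipeline/rs_exon_links.tsv", comment.char = "#")

genome <- read_genome("scratch/experiment/genome.fa")
ann <- derive_introns(read_annotation("scratch/experiment/annotation.gff3"))
cons <- read_track("scratch/experiment/conservation.bedGraph", "conservation")
manifest <- read_manifest("scratch/experiment/manifest.tsv")
cov <- read_track(manifest$coverage_path[1], "coverage")

## conservation profiles: canonical acceptors vs RSSs vs random introns
acceptors <- with(ann$introns,
                  data.frame(chrom = chrom, strand = strand,
                             pos = ifelse(strand == "+", end, start)))
groups <- list(
  canonical_acceptor = acceptors,
  rss = data.frame(chrom = rss$chrom, strand = rss$strand,
                   pos = rss$rs_point),
  random_intronic = random_intronic_sites(ann$introns, 200, seed = 7))
prof <- do.call(rbind, lapply(names(groups), function(g) {
  p <- conservation_profile(groups[[g]], cons, half_window = 15)
  data.frame(group = g, offset = as.integer(names(p)), mean_score = p)
}))
write.table(prof, "results/03_conservation_profiles.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)

## sequence probability matrix around detected RS points
ppm <- sequence_probability_matrix(groups$rss, genome, half_window = 10)
write.table(data.frame(base = rownames(ppm), ppm, check.names = FALSE),
            "results/03_rss_ppm.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)

## cryptic-exon coverage enrichment over associated RS-exons
cry <- cryptic_exon_flag(links[links$associated, ], cov)
write.table(cry, "results/03_cryptic_exons.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)

## donor-class enrichment among gained/lost RSSs
enr <- donor_class_enrichment(diff)
write.table(enr, "results/03_donor_enrichment.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)

## AS overlap: synthetic gene->AS-type table with RS genes enriched for CE
set.seed(11)
universe <- ann$genes$gene_id
rs_genes <- unique(rss$gene_id)
as_events <- rbind(
  data.frame(gene_id = sample(universe, 8), as_type = "TE"),
  data.frame(gene_id = sample(universe, 6), as_type = "TS"),
  data.frame(gene_id = sample(rs_genes, min(8, length(rs_genes))),
             as_type = "CE"),
  data.frame(gene_id = sample(universe, 4), as_type = "IR"))
asx <- as_overlap_enrichment(rs_genes, as_events, universe)
write.table(asx, "results/03_as_overlap.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)

message("Cryptic RS-exons: ", sum(cry$cryptic), " of ", nrow(cry),
        " associated exons (fold > 2).")
message("Most enriched AS type: ",
        asx$label[which.max(asx$neg_log10_p)],
        sprintf(" (-log10 P = %.2f)", max(asx$neg_log10_p)))
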