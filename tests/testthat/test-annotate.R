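# RS-exon association, cryptic-exon calling, conservation strata and
# profiles, sequence probability matrices, and enrichment statistics.

rss_row <- function(rs_point, gene_id = "gA", chrom = "chrA", strand = "+",
                    intron_start = 100L, intron_end = 900L) {
  data.frame(rss_id = paste0(gene_id, ":", rs_point), gene_id = gene_id,
             chrom = chrom, strand = strand, rs_point = rs_point,
             intron_start = intron_start, intron_end = intron_end,
             stringsAsFactors = FALSE)
}

test_that("RS-exon association requires an exon starting at the RS point", {
  ann <- derive_introns(make_ann(rbind(
    exon_row("gA.t1", "gA", "chrA", "+", c(0, 900), c(100, 1000)),
    exon_row("gA.t2", "gA", "chrA", "+", c(0, 500, 900),
             c(100, 587, 1000)))))
  hit <- associate_rs_exon(rss_row(500L), ann)
  expect_true(hit$associated)
  expect_equal(c(hit$exon_start, hit$exon_end), c(500L, 587L))

  # no exon in the intron downstream of the point: "zero-length" mode
  miss <- associate_rs_exon(rss_row(300L), ann)
  expect_false(miss$associated)

  # off-by-five exon start is rejected at tolerance 0, accepted at 5
  near <- associate_rs_exon(rss_row(495L), ann)
  expect_false(near$associated)
  expect_true(associate_rs_exon(rss_row(495L), ann,
                                tolerance_nt = 5)$associated)

  # minus strand: the RS-exon's 5' start is its genomic end
  ann_m <- derive_introns(make_ann(rbind(
    exon_row("gM.t1", "gM", "chrM", "-", c(0, 900), c(100, 1000)),
    exon_row("gM.t2", "gM", "chrM", "-", c(0, 420, 900),
             c(100, 500, 1000)))))
  hm <- associate_rs_exon(rss_row(500L, gene_id = "gM", chrom = "chrM",
                                  strand = "-"), ann_m)
  expect_true(hm$associated)
  expect_equal(c(hm$exon_start, hm$exon_end), c(420L, 500L))
})

test_that("cryptic exons are called by flanking-normalized coverage", {
  links <- data.frame(rss_id = "gA:500", gene_id = "gA", chrom = "chrA",
                      strand = "+", rs_point = 500L, intron_start = 100L,
                      intron_end = 900L, associated = TRUE,
                      exon_start = 500L, exon_end = 600L)
  # exon mean 20, flanks [400,500) and [600,700) mean 5
  tr <- make_track(data.frame(chrom = "chrA", start = c(400, 500, 600),
                              end = c(500, 600, 700), value = c(5, 20, 5)))
  out <- cryptic_exon_flag(links, tr)
  expect_equal(out$coverage_fold, 20.5 / 5.5)
  expect_true(out$cryptic)

  flat <- make_track(data.frame(chrom = "chrA", start = 0, end = 1000,
                                value = 7))
  expect_equal(cryptic_exon_flag(links, flat)$coverage_fold, 1)
  expect_false(cryptic_exon_flag(links, flat)$cryptic)

  silent <- make_track(data.frame(chrom = "chrZ", start = 0, end = 1,
                                  value = 1))
  expect_equal(cryptic_exon_flag(links, silent)$coverage_fold, 1)

  un <- links; un$associated <- FALSE
  expect_error(cryptic_exon_flag(un, tr), "associated")
})

test_that("conservation strata split strictly at the threshold", {
  cat1 <- data.frame(rss_id = paste0("r", 1:3),
                     conservation_mean = c(0.9, 0.1, 0.45))
  out <- stratify_conservation(cat1)
  expect_equal(as.character(out$cons_stratum), c("high", "low", "low"))
  expect_equal(attr(out, "n_boundary"), 1L)
})

test_that("conservation profiles align and average site windows", {
  const <- make_track(data.frame(chrom = "chrA", start = 0, end = 400,
                                 value = 0.7), kind = "conservation")
  sites <- data.frame(chrom = "chrA", strand = "+", pos = c(100L, 200L))
  prof <- conservation_profile(sites, const, half_window = 5)
  expect_equal(unname(prof), rep(0.7, 11))
  expect_equal(names(prof), as.character(-5:5))

  # identity: track value = position index, single site
  idx <- make_track(data.frame(chrom = "chrA", start = 0:399, end = 1:400,
                               value = (0:399) / 1000),
                    kind = "conservation")
  one <- conservation_profile(data.frame(chrom = "chrA", strand = "+",
                                         pos = 100L), idx, half_window = 3)
  expect_equal(unname(one), (97:103) / 1000)
  # minus strand reads the window mirrored
  onem <- conservation_profile(data.frame(chrom = "chrA", strand = "-",
                                          pos = 100L), idx, half_window = 3)
  expect_equal(unname(onem), (102:96) / 1000)

  # two sites average per offset
  two <- conservation_profile(data.frame(chrom = "chrA", strand = "+",
                                         pos = c(100L, 300L)),
                              idx, half_window = 2)
  expect_equal(unname(two), (c(98, 99, 100, 101, 102) + 200 +
                               c(98, 99, 100, 101, 102)) / 2 / 1000)

  # group-union profile is the size-weighted mean of group profiles
  gA <- data.frame(chrom = "chrA", strand = "+", pos = c(50L, 150L, 250L))
  gB <- data.frame(chrom = "chrA", strand = "+", pos = 350L)
  pu <- conservation_profile(rbind(gA, gB), idx, half_window = 4)
  pa <- conservation_profile(gA, idx, half_window = 4)
  pb <- conservation_profile(gB, idx, half_window = 4)
  expect_equal(pu, (3 * pa + 1 * pb) / 4)

  expect_error(conservation_profile(gA[0, ], idx), "empty")
})

test_that("random intronic control sites stay inside their introns", {
  introns <- data.frame(chrom = "chrA", strand = "+",
                        start = c(100L, 1000L), end = c(600L, 1800L),
                        gene_id = c("g1", "g2"))
  s <- random_intronic_sites(introns, 200, margin = 20, seed = 5)
  expect_equal(nrow(s), 200L)
  inside <- vapply(seq_len(nrow(s)), function(i)
    any(s$pos[i] >= introns$start + 20 & s$pos[i] <= introns$end - 20),
    logical(1))
  expect_true(all(inside))
  expect_identical(random_intronic_sites(introns, 200, seed = 5), s)
})

test_that("position probability matrices are column-stochastic", {
  g <- make_genome(list(chrA = "AAAACAGGTTTTT"))
  # plus-strand site with boundary at 7: motif CAG at [4,7), donor GT
  sites <- data.frame(chrom = "chrA", strand = "+", pos = 7L)
  ppm <- sequence_probability_matrix(sites, g, half_window = 3)
  expect_equal(dim(ppm), c(4L, 7L))
  expect_equal(unname(colSums(ppm)), rep(1, 7), tolerance = 1e-12)
  # single sequence gives one-hot columns: C at -3, G at -1, G at 0, T at 1
  expect_equal(ppm["C", "-3"], 1)
  expect_equal(ppm["G", "-1"], 1)
  expect_equal(ppm["G", "0"], 1)
  expect_equal(ppm["T", "1"], 1)

  # half GT / half AT donors -> split at offset 0
  g2 <- make_genome(list(c1 = "AAAACAGGTTTTT", c2 = "AAAACAGATTTTT"))
  sites2 <- data.frame(chrom = c("c1", "c2"), strand = "+", pos = 7L)
  ppm2 <- sequence_probability_matrix(sites2, g2, half_window = 2)
  expect_equal(ppm2["G", "0"], 0.5)
  expect_equal(ppm2["A", "0"], 0.5)
  expect_equal(ppm2["T", "1"], 1)

  # minus-strand site reads the reverse complement; aligned AG at -2,-1.
  # Transcription context AACAG|GTT sits at genomic [3,11) on the minus
  # strand, so the boundary (first donor base G) is genomic position 6.
  g3 <- make_genome(list(c3 = paste0("TTT", rc("AACAGGTT"), "TT")))
  sites3 <- data.frame(chrom = "c3", strand = "-", pos = 6L)
  ppm3 <- sequence_probability_matrix(sites3, g3, half_window = 2)
  expect_equal(ppm3["A", "-2"], 1)
  expect_equal(ppm3["G", "-1"], 1)

  # Ns drop out of the denominator
  gn <- make_genome(list(c1 = "AAAACAGGTTTTT", c2 = "AAAANAGATTTTT"))
  ppmn <- sequence_probability_matrix(
    data.frame(chrom = c("c1", "c2"), strand = "+", pos = 7L),
    gn, half_window = 3)
  expect_equal(ppmn["C", "-3"], 1)  # only the non-N base counts
  expect_equal(unname(colSums(ppmn)), rep(1, 7), tolerance = 1e-12)
})

test_that("donor-class enrichment applies two-tailed Fisher tests", {
  # 10 of 12 lost RSSs match AN vs 30 of 100 unchanged
  diff <- data.frame(
    rss_id = paste0("r", 1:112),
    status = rep(c("lost", "unchanged"), c(12, 100)),
    donor2 = c(rep("AT", 10), rep("GT", 2), rep("AC", 30), rep("GT", 70)),
    stringsAsFactors = FALSE)
  res <- donor_class_enrichment(diff, patterns = "AN",
                                directions = "lost")
  expect_equal(unlist(res[, c("n_dir_match", "n_dir_other",
                              "n_unch_match", "n_unch_other")],
                      use.names = FALSE), c(10, 2, 30, 70))
  expect_equal(res$p_value, oracle_fisher_two_sided(10, 2, 30, 70),
               tolerance = 1e-10)
  expect_lt(res$p_value, 1e-3)
  expect_equal(res$neg_log10_p, -log10(res$p_value))

  # pattern matching nothing is flagged with P = 1
  none <- donor_class_enrichment(
    data.frame(rss_id = paste0("r", 1:10),
               status = rep(c("lost", "unchanged"), each = 5),
               donor2 = "GT"), patterns = "CN", directions = "lost")
  expect_equal(none$p_value, 1)
  expect_true(none$flagged)

  # balanced table: P = 1, OR = 1
  bal <- donor_class_enrichment(
    data.frame(rss_id = paste0("r", 1:20),
               status = rep(c("lost", "unchanged"), each = 10),
               donor2 = rep(c("AT", "GT"), 10)),
    patterns = "AN", directions = "lost")
  expect_equal(bal$p_value, 1)
})

test_that("Fisher P matches exhaustive hypergeometric summation", {
  set.seed(12)
  for (i in 1:60) {
    cells <- c(sample(0:12, 2, replace = TRUE),
               sample(0:12, 2, replace = TRUE))
    got <- stats::fisher.test(matrix(cells, 2, byrow = TRUE))$p.value
    want <- oracle_fisher_two_sided(cells[1], cells[2], cells[3], cells[4])
    expect_equal(got, want, tolerance = 1e-10)
  }
})

test_that("AS-overlap enrichment is an upper-tail hypergeometric", {
  universe <- paste0("g", 1:100)
  typed <- data.frame(gene_id = paste0("g", 1:10), as_type = "CE")
  res <- as_overlap_enrichment(paste0("g", 1:10), typed, universe)
  expect_equal(res$n_overlap, 10)
  expect_equal(res$p_value, 1 / choose(100, 10), tolerance = 1e-12)
  expect_equal(res$p_value,
               oracle_hyper_upper(10, 10, 90, 10), tolerance = 1e-12)

  miss <- as_overlap_enrichment(paste0("g", 51:60), typed, universe)
  expect_equal(miss$n_overlap, 0)
  expect_equal(miss$p_value, 1)

  sat <- as_overlap_enrichment(universe, typed, universe)
  expect_equal(sat$n_overlap, 10)
  expect_equal(sat$p_value, 1)

  expect_error(as_overlap_enrichment(c("g1", "nope"), typed, universe),
               "not in universe")
})
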