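# Filter criteria: conservation, overhang, sawtooth + permutation test,
# poly(A) subtraction, and the assembled filter chain.

# Minimal catalog row for filter-level tests.
cand <- function(chrom = "chrF", strand = "+", intron_start = 0L,
                 intron_end = 2000L, rs_point = 1000L, gene_id = "gF",
                 overhang = 20L, motif_pass = TRUE, reads = 10L) {
  data.frame(sample_id = "s", rss_id = paste0(gene_id, ":", rs_point),
             chrom = chrom, strand = strand, gene_id = gene_id,
             intron_start = intron_start, intron_end = intron_end,
             donor_3p = if (strand == "+") intron_start else intron_end,
             rs_point = rs_point, unique_reads = reads,
             max_overhang = overhang, motif3 = "CAG", donor2 = "GT",
             motif_pass = motif_pass,
             motif_reason = ifelse(motif_pass, "", "not_yag"),
             stringsAsFactors = FALSE)
}

# Coverage track that is `up` before the breakpoint and `down` after,
# over intron [0, 2000) with rs_point 1000.
step_track <- function(up, down, chrom = "chrF") {
  make_track(data.frame(chrom = chrom, start = c(0, 1000),
                        end = c(1000, 2000), value = c(up, down)))
}

test_that("conservation score is the 5-nt motif mean with a strict cutoff", {
  # per-base scores 0.8,0.7,0.6,0.5,0.4 over the motif [997,1002)
  tr <- make_track(data.frame(chrom = "chrF", start = 997:1001,
                              end = 998:1002,
                              value = c(0.8, 0.7, 0.6, 0.5, 0.4)),
                   kind = "conservation")
  out <- conservation_filter(cand(), tr)
  expect_equal(out$conservation_mean, 0.6)
  expect_true(out$cons_pass)
  expect_false(out$cons_warn)

  flat <- make_track(data.frame(chrom = "chrF", start = 990, end = 1010,
                                value = 0.5), kind = "conservation")
  out <- conservation_filter(cand(), flat)
  expect_equal(out$conservation_mean, 0.5)
  expect_false(out$cons_pass)  # strict >

  empty <- make_track(data.frame(chrom = "chrOther", start = 0, end = 1,
                                 value = 1), kind = "conservation")
  out <- conservation_filter(cand(), empty)
  expect_equal(out$conservation_mean, 0)
  expect_false(out$cons_pass)
  expect_true(out$cons_warn)

  # minus strand reads the window on the other side of the boundary
  tr_m <- make_track(data.frame(chrom = "chrF", start = 998:1002,
                                end = 999:1003, value = 0.9),
                     kind = "conservation")
  out <- conservation_filter(cand(strand = "-"), tr_m)
  expect_equal(out$conservation_mean, 0.9)
})

test_that("overhang must strictly exceed 5 nt", {
  cfg <- filter_config()
  expect_false(overhang_filter(cand(overhang = 5L), cfg)$overhang_pass)
  expect_true(overhang_filter(cand(overhang = 6L), cfg)$overhang_pass)
  expect_false(overhang_filter(cand(overhang = 0L), cfg)$overhang_pass)
})

test_that("sawtooth fold uses pseudo-counted window means", {
  cfg <- filter_config(seed = 5)
  out <- sawtooth_test(cand(), step_track(10, 4), cfg)
  expect_equal(out$sawtooth_up, 10)
  expect_equal(out$sawtooth_down, 4)
  expect_equal(out$sawtooth_fold, 10.5 / 4.5)
  expect_true(out$sawtooth_fold > 2)

  out <- sawtooth_test(cand(), step_track(8, 4), cfg)
  expect_equal(out$sawtooth_fold, 8.5 / 4.5)
  expect_false(out$sawtooth_pass)  # two-fold not met

  out <- sawtooth_test(cand(), step_track(5, 5), cfg)
  expect_equal(out$sawtooth_fold, 1)
  expect_false(out$sawtooth_pass)
})

test_that("minus-strand windows flip with transcription orientation", {
  cfg <- filter_config(seed = 5)
  # same genomic coverage; on the minus strand "upstream" is genomically
  # right of the breakpoint
  out <- sawtooth_test(cand(strand = "-"), step_track(10, 4), cfg)
  expect_equal(out$sawtooth_up, 4)
  expect_equal(out$sawtooth_down, 10)
  expect_true(out$sawtooth_fold < 1)
})

test_that("short introns are untestable, a distinct failure reason", {
  cfg <- filter_config()
  out <- sawtooth_test(cand(intron_start = 960L, intron_end = 1040L),
                       step_track(10, 4), cfg)
  expect_true(out$sawtooth_untestable)
  expect_false(out$sawtooth_pass)
})

test_that("a clean strong step attains the permutation floor 1/(n+1)", {
  cfg <- filter_config(seed = 5, n_perm = 1000)
  set.seed(88)
  v <- c(rpois(4000, 50), rpois(4000, 5))
  path <- tempfile(fileext = ".bedGraph")
  write_bedgraph(list(chrF = v), path)
  tr <- read_track(path, "coverage")
  out <- sawtooth_test(cand(intron_end = 8000L, rs_point = 4000L), tr, cfg)
  expect_equal(out$sawtooth_p, 1 / 1001)
  expect_true(out$sawtooth_pass)
})

test_that("permutation p is deterministic per seed and candidate-order free", {
  cfg <- filter_config(seed = 42)
  tr <- step_track(10, 4)
  two <- rbind(cand(rs_point = 900L), cand(rs_point = 1100L))
  a <- sawtooth_test(two, tr, cfg)
  b <- sawtooth_test(two[2:1, ], tr, cfg)
  expect_equal(a$sawtooth_p, rev(b$sawtooth_p))
  expect_equal(sawtooth_test(two, tr, cfg)$sawtooth_p, a$sawtooth_p)
  cfg2 <- filter_config(seed = 43)
  expect_false(identical(sawtooth_test(two, tr, cfg2)$sawtooth_p,
                         a$sawtooth_p))
})

test_that("mean observed fold increases with the planted step size", {
  cfg <- filter_config(seed = 3)
  mean_fold <- vapply(c(1, 2, 4, 8), function(f) {
    folds <- vapply(1:10, function(i) {
      set.seed(1000 + i)  # matched coverage noise across fold levels
      v <- c(rpois(2000, 40), rpois(2000, 40 / f))
      p <- tempfile(fileext = ".bedGraph")
      write_bedgraph(list(chrF = v), p)
      tr <- read_track(p, "coverage")
      sawtooth_test(cand(intron_end = 4000L, rs_point = 2000L), tr,
                    cfg)$sawtooth_fold
    }, numeric(1))
    mean(folds)
  }, numeric(1))
  expect_true(all(diff(mean_fold) > 0))
})

test_that("permutation p is calibrated on flat null coverage", {
  cfg <- filter_config(seed = 19, n_perm = 200)
  cal <- sawtooth_null_calibration(n_sites = 100, intron_length = 2000,
                                   lambda = 10, cfg = cfg, seed = 21)
  expect_true(cal$fraction_significant <= 0.06)
  expect_true(all(cal$p_values >= 1 / 201))
})

test_that("annotated intron-internal exons are masked out of the windows", {
  cfg <- filter_config(seed = 4)
  # strong included exon [1000,1100) inside the down window
  v <- c(rep(40, 1000), rep(240, 100), rep(10, 900))
  p <- tempfile(fileext = ".bedGraph")
  write_bedgraph(list(chrF = v), p)
  tr <- read_track(p, "coverage")
  ann <- derive_introns(make_ann(rbind(
    exon_row("gF.t1", "gF", "chrF", "+", c(-100, 2000) + 100, c(0, 2100) + 100),
    exon_row("gF.t2", "gF", "chrF", "+", c(0, 1000, 2100), c(100, 1100, 2200)))))
  no_mask <- sawtooth_test(cand(intron_start = 100L, intron_end = 2100L),
                           tr, cfg)
  masked <- sawtooth_test(cand(intron_start = 100L, intron_end = 2100L),
                          tr, cfg, ann = ann)
  expect_lt(no_mask$sawtooth_fold, 2)    # contaminated by exon signal
  expect_gt(masked$sawtooth_fold, 3)     # intronic densities only
})

test_that("poly(A) subtraction removes candidates seen in poly(A) data", {
  cfg <- filter_config()
  cat1 <- rbind(cand(rs_point = 500L), cand(rs_point = 1200L))
  polya <- cand(rs_point = 500L, reads = 3L)
  out <- polya_subtraction(cat1, list(polya), cfg)
  expect_equal(out$in_polya, c(TRUE, FALSE))
  out0 <- polya_subtraction(cat1, list(), cfg)
  expect_false(any(out0$in_polya))
  zero <- polya; zero$unique_reads <- 0L
  out_z <- polya_subtraction(cat1, list(zero), cfg)
  expect_false(any(out_z$in_polya))
})

test_that("the filter chain is conjunctive with consistent stage counts", {
  cfg <- filter_config(seed = 10)
  chroms <- c("chrF", "chrG", "chrH", "chrI")
  cons <- make_track(data.frame(chrom = chroms, start = 0, end = 2000,
                                value = 0.9), kind = "conservation")
  cov <- make_track(data.frame(chrom = rep(chroms, each = 2),
                               start = c(0, 1000), end = c(1000, 2000),
                               value = c(40, 5)))
  cat1 <- rbind(cand(chrom = "chrF", gene_id = "gF"),
                cand(chrom = "chrG", gene_id = "gG", motif_pass = FALSE),
                cand(chrom = "chrH", gene_id = "gH", overhang = 5L),
                cand(chrom = "chrI", gene_id = "gI"))
  out <- apply_filters(cat1, cons, cov, cfg,
                       polya_catalogs = list(cand(chrom = "chrI",
                                                  gene_id = "gI")))
  expect_equal(out$status, c("pass", "fail", "fail", "fail"))
  expect_equal(out$flags, c("pass", "motif", "overhang", "polya"))
  counts <- attr(out, "stage_counts")
  expect_true(all(diff(counts) <= 0))
  # stage drops match first-failure reason tallies
  expect_equal(counts[["candidates"]] - counts[["motif"]],
               sum(grepl("^motif", out$flags)))
  expect_equal(counts[["overhang"]] - counts[["sawtooth"]],
               sum(grepl("^sawtooth", out$flags)))
  expect_equal(counts[["sawtooth"]] - counts[["polya"]],
               sum(out$flags == "polya"))
  expect_equal(counts[["polya"]], sum(out$status == "pass"))

  # determinism of the full chain
  out2 <- apply_filters(cat1, cons, cov, cfg,
                        polya_catalogs = list(cand(chrom = "chrI",
                                                   gene_id = "gI")))
  expect_identical(as.data.frame(out), as.data.frame(out2))
})
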