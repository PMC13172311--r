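# Independent oracles used to check package results. These deliberately
# avoid the package's own code paths.

# Reverse complement, independent of the package's helper.
rc <- function(s) {
  paste(rev(strsplit(chartr("ACGTN", "TGCAN", s), "")[[1]]), collapse = "")
}

# Closed-form pooled-variance two-sample two-tailed Student's t-test.
oracle_t_pooled <- function(x, y) {
  nx <- length(x); ny <- length(y)
  sp2 <- (sum((x - mean(x))^2) + sum((y - mean(y))^2)) / (nx + ny - 2)
  t <- (mean(x) - mean(y)) / sqrt(sp2 * (1 / nx + 1 / ny))
  list(t = t, p = 2 * stats::pt(-abs(t), nx + ny - 2))
}

# Two-sided Fisher exact P by exhaustive hypergeometric summation.
# Probabilities come straight from lgamma; the conventional two-sided
# rule sums all tables with probability <= p(observed) * (1 + 1e-7).
oracle_fisher_two_sided <- function(a, b, c_, d) {
  r1 <- a + b; r2 <- c_ + d; c1 <- a + c_; n <- r1 + r2
  lprob <- function(x) {
    lgamma(r1 + 1) - lgamma(x + 1) - lgamma(r1 - x + 1) +
      lgamma(r2 + 1) - lgamma(c1 - x + 1) - lgamma(r2 - c1 + x + 1) -
      (lgamma(n + 1) - lgamma(c1 + 1) - lgamma(n - c1 + 1))
  }
  xs <- max(0, c1 - r2):min(r1, c1)
  pr <- exp(vapply(xs, lprob, numeric(1)))
  pobs <- pr[xs == a]
  min(1, sum(pr[pr <= pobs * (1 + 1e-7)]))
}

# Upper-tail hypergeometric P(X >= x) from lgamma directly.
oracle_hyper_upper <- function(x, m, n_other, k) {
  xs <- x:min(m, k)
  if (x <= max(0, k - n_other)) return(1)
  lch <- function(n, r) lgamma(n + 1) - lgamma(r + 1) - lgamma(n - r + 1)
  sum(exp(lch(m, xs) + lch(n_other, k - xs) - lch(m + n_other, k)))
}

# Brute-force RSS scan: for every intron, every interior boundary with at
# least `margin` nt to both intron ends, read the acceptor trinucleotide
# by plain string ops and report positions matching [CT]AG.
brute_force_rss_scan <- function(chrom_seqs, introns, margin = 3) {
  hits <- list()
  for (i in seq_len(nrow(introns))) {
    it <- introns[i, ]
    s <- as.character(chrom_seqs[[it$chrom]])
    for (p in (it$start + margin):(it$end - margin)) {
      m3 <- if (it$strand == "+") substr(s, p - 2, p)  # 0-based [p-3, p)
            else rc(substr(s, p + 1, p + 3))           # 0-based [p, p+3)
      if (grepl("^[CT]AG$", m3))
        hits[[length(hits) + 1L]] <- data.frame(
          gene_id = it$gene_id, rs_point = p, motif3 = m3,
          stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, hits)
  if (is.null(out)) out <- data.frame(gene_id = character(),
                                      rs_point = integer(),
                                      motif3 = character())
  out[order(out$gene_id, out$rs_point), , drop = FALSE]
}
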