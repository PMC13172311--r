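# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

# Evaluate `code` under a fixed RNG seed, restoring global RNG state after.
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  force(code)
}

# Stable 31-bit hash of a string; used to derive per-sample / per-site
# RNG substreams so results do not depend on processing order.
str_hash31 <- function(x) {
  h <- 0
  for (b in utf8ToInt(x)) h <- (h * 131 + b) %% 2147483647
  as.integer(h)
}

# Derive a reproducible child seed (< 2^31) from a master seed plus
# arbitrary string/numeric parts.
derive_seed <- function(seed, ...) {
  h <- as.numeric(as.integer(seed) %% 2147483647L)
  for (part in list(...)) {
    key <- if (is.character(part)) str_hash31(part)
    else as.integer(abs(as.numeric(part)) %% 2147483647)
    h <- (h * 48271 + as.numeric(key) + 1) %% 2147483647
  }
  as.integer(h)
}

# Reverse complement of plain character DNA strings (ACGTN alphabet).
revcomp <- function(x) {
  vapply(x, function(s) {
    paste(rev(strsplit(chartr("ACGTNacgtn", "TGCANtgcan", s), "")[[1]]),
          collapse = "")
  }, character(1), USE.NAMES = FALSE)
}

# Write a data.frame as TSV with '# '-prefixed header lines, atomically
# (written to a temp path in the same directory, then renamed).
write_tsv_header <- function(df, path, header_lines = character()) {
  tmp <- paste0(path, ".tmp")
  con <- file(tmp, "w")
  if (length(header_lines)) writeLines(paste0("# ", header_lines), con)
  close(con)
  suppressWarnings(utils::write.table(
    df, tmp, append = TRUE, sep = "\t", quote = FALSE,
    row.names = FALSE, col.names = TRUE))
  file.rename(tmp, path)
  invisible(path)
}

# Standard metadata header for pipeline outputs.
output_header <- function(seed = NA, params = list()) {
  pstr <- if (length(params))
    paste(names(params), vapply(params, function(p) paste(format(p), collapse = ","),
                                character(1)), sep = "=", collapse = " ")
  else ""
  c(paste0("recsplice ", as.character(utils::packageVersion("recsplice"))),
    paste0("seed=", seed),
    paste0("params: ", pstr))
}
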