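# Fixture builders shared across test files. All fixtures are generated
# in code; PED/MAP files are written to tempdir() when a test needs to
# exercise the parsers.

# dose (0/1/2/NA) -> two allele tokens, "0 0" when missing
dose_alleles <- function(d, risk = "B", wild = "A") {
  ifelse(is.na(d), "0 0",
         c(paste(wild, wild), paste(wild, risk), paste(risk, risk))[d + 1])
}

# Write PED/MAP files for one trio per row of (M, P, C) dose vectors.
# Extra columns of `extra` (a list of dose vectors, one per extra SNP)
# become additional null SNPs. Returns list(ped =, map =) paths.
write_trio_fixture <- function(M, P, C, extra = list(), dir = tempfile("ped")) {
  dir.create(dir)
  n <- length(M)
  doses <- c(list(M = M, P = P, C = C), lapply(extra, identity))
  n_snp <- 1L + length(extra)
  lines <- character(3L * n)
  for (i in seq_len(n)) {
    fid <- sprintf("F%03d", i)
    gm <- dose_alleles(M[i]); gf <- dose_alleles(P[i]); gc <- dose_alleles(C[i])
    for (k in seq_along(extra)) {
      gm <- paste(gm, dose_alleles(extra[[k]]$M[i]))
      gf <- paste(gf, dose_alleles(extra[[k]]$P[i]))
      gc <- paste(gc, dose_alleles(extra[[k]]$C[i]))
    }
    lines[3 * i - 2] <- paste(fid, "mom", "0", "0", "2", "1", gm)
    lines[3 * i - 1] <- paste(fid, "dad", "0", "0", "1", "1", gf)
    lines[3 * i]     <- paste(fid, "kid", "dad", "mom", "0", "2", gc)
  }
  ped <- file.path(dir, "trios.ped")
  map <- file.path(dir, "trios.map")
  writeLines(lines, ped)
  writeLines(sprintf("1\tSNP%03d\t0\t%d", seq_len(n_snp), 1000L * seq_len(n_snp)),
             map)
  list(ped = ped, map = map)
}

# doses realizing given 15-cell counts, in canonical cell order
doses_from_counts <- function(counts) {
  cl <- triopoo::triad_cells()
  idx <- rep(cl$cell, counts)
  data.frame(M = cl$M[idx], P = cl$P[idx], C = cl$C[idx])
}

# random non-degenerate cell table (counts in all 15 cells possible)
random_cell_table <- function(n = 200) {
  w <- stats::rgamma(15, shape = 2)
  counts <- as.integer(stats::rmultinom(1, n, w / sum(w)))
  triopoo::cell_table(counts)
}

# write a snp-config TSV
write_snp_config <- function(df, path = tempfile(fileext = ".tsv")) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}
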