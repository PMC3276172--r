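# Independent oracles and small fixture builders used across the suite.

# Brute-force mean pairwise difference: explicit double loop over pairs
# and sites, deliberately independent of the package's column-counting
# implementation.
pi_bruteforce <- function(aln) {
  m <- aln$mat
  n <- nrow(m)
  valid <- c("A", "C", "G", "T")
  tot <- 0
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      ok <- m[i, ] %in% valid & m[j, ] %in% valid
      tot <- tot + sum(m[i, ok] != m[j, ok])
    }
  }
  tot / choose(n, 2)
}

random_alignment <- function(n, L) {
  locus_alignment(matrix(sample(c("A", "C", "G", "T"), n * L,
                                replace = TRUE),
                         nrow = n))
}

# Small aligned FASTA on disk for IO tests
write_tmp_fasta <- function(seqs, names = NULL) {
  if (is.null(names)) names <- paste0("s", seq_along(seqs))
  path <- tempfile(fileext = ".fasta")
  writeLines(as.vector(rbind(paste0(">", names), seqs)), path)
  path
}
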