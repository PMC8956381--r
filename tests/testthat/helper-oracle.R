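# Independent brute-force affine-gap DP oracle, written before (and kept
# independent of) the package aligner. Semi-global: reference overhangs at
# both ends are free, the query is aligned end to end. A gap of length L
# costs gap_open + (L - 1) * gap_extend. Score only, O(nm) three-state DP.
affine_oracle_score <- function(q, r, match = 1, mismatch = -1,
                                gap_open = -4, gap_extend = -1) {
  qs <- strsplit(q, "")[[1L]]
  rs <- strsplit(r, "")[[1L]]
  n <- length(qs); m <- length(rs)
  NEG <- -1e18
  M <- matrix(NEG, n + 1L, m + 1L)  # ends with q[i] ~ r[j]
  X <- matrix(NEG, n + 1L, m + 1L)  # ends with q[i] ~ gap (insertion)
  Y <- matrix(NEG, n + 1L, m + 1L)  # ends with gap ~ r[j] (deletion)
  M[1L, ] <- 0                      # free leading reference overhang
  for (i in seq_len(n)) {
    X[i + 1L, 1L] <- max(M[i, 1L] + gap_open, X[i, 1L] + gap_extend)
    for (j in seq_len(m)) {
      s <- if (qs[i] == rs[j]) match else mismatch
      M[i + 1L, j + 1L] <- s + max(M[i, j], X[i, j], Y[i, j])
      X[i + 1L, j + 1L] <- max(M[i, j + 1L] + gap_open,
                               Y[i, j + 1L] + gap_open,
                               X[i, j + 1L] + gap_extend)
      Y[i + 1L, j + 1L] <- max(M[i + 1L, j] + gap_open,
                               X[i + 1L, j] + gap_open,
                               Y[i + 1L, j] + gap_extend)
    }
  }
  max(M[n + 1L, ], X[n + 1L, ])     # free trailing reference overhang
}

random_dna <- function(n) paste(sample(c("A", "C", "G", "T"), n, replace = TRUE),
                                collapse = "")

# Write a tree data.frame (haplogroup, parent, variants) to a temp TSV and
# load it through the public loader.
make_tree <- function(haplogroup, parent, variants) {
  df <- data.frame(haplogroup = haplogroup, parent = parent,
                   variants = variants, stringsAsFactors = FALSE)
  path <- withr::local_tempfile(fileext = ".tsv",
                                .local_envir = parent.frame())
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  load_tree(path)
}

# Cached packaged reference for the whole suite.
REF <- load_reference()

# Random valid variant tokens for round-trip properties.
random_variant_tokens <- function(n) {
  kinds <- sample(c("ts", "tv", "ins", "del"), n, replace = TRUE,
                  prob = c(0.5, 0.2, 0.15, 0.15))
  pos <- sample.int(16569L, n, replace = TRUE)
  bang <- ifelse(stats::runif(n) < 0.1, "!", "")
  vapply(seq_len(n), function(i) {
    switch(kinds[i],
      ts  = paste0(pos[i], bang[i]),
      tv  = paste0(pos[i], sample(c("A", "C", "G", "T"), 1L), bang[i]),
      ins = paste0(pos[i], ".", sample(1:3, 1L),
                   paste(sample(c("A", "C", "G", "T"),
                                sample(1:2, 1L), replace = TRUE),
                         collapse = ""), bang[i]),
      del = paste0(pos[i], "d", bang[i]))
  }, "")
}
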