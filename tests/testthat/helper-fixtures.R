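# Small fixtures built in code, shared across test files.

# a tiny valid count matrix with two groups
tiny_counts <- function(n_genes = 6, n_samples = 4, seed = 1) {
  withr::with_seed(seed, {
    m <- matrix(rpois(n_genes * n_samples, 50), n_genes, n_samples,
                dimnames = list(sprintf("g%02d", seq_len(n_genes)),
                                sprintf("s%02d", seq_len(n_samples))))
    count_matrix(m, rep(c("HC", "PC"), each = n_samples / 2))
  })
}

# a transcript model (0-based half-open exons)
tx <- function(id, chrom, strand, exons, gene_id = NA_character_) {
  list(id = id, gene_id = gene_id, chrom = chrom, strand = strand,
       exons = matrix(exons, ncol = 2, byrow = TRUE))
}

# an annotation set holding just the given transcripts (no genes)
tx_set <- function(...) {
  annotation_set(
    data.frame(id = character(0), chrom = character(0), start = integer(0),
               end = integer(0), strand = character(0), biotype = character(0)),
    list(...))
}

# brute-force TOM by triple loop (the oracle for build_network)
tom_brute <- function(a) {
  n <- nrow(a)
  k <- rowSums(a) - diag(a)
  tom <- matrix(0, n, n)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i == j) { tom[i, j] <- 1; next }
    s <- 0
    for (u in seq_len(n)) if (u != i && u != j) s <- s + a[i, u] * a[u, j]
    tom[i, j] <- (s + a[i, j]) / (min(k[i], k[j]) + 1 - a[i, j])
  }
  tom
}

# brute-force Benjamini-Hochberg from the definition
bh_brute <- function(p) {
  m <- length(p)
  o <- order(p)
  q <- numeric(m)
  for (i in seq_len(m)) {
    j <- which(o == i)   # rank of p[i]
    q[i] <- min(1, min(m * p[o][j:m] / (j:m)))
  }
  q
}
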