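# Independent brute-force oracles used to check the exact tests and the
# motif scanner. These deliberately avoid the code paths they verify.

# all 4-mers matching WRCY or RGYW, by explicit expansion of the degenerate
# letters
wrcy_kmers <- local({
  W <- c("A", "T"); R <- c("A", "G"); Y <- c("C", "T")
  fwd <- as.vector(outer(outer(outer(W, R, paste0), "C", paste0), Y, paste0))
  rev <- as.vector(outer(outer(outer(R, "G", paste0), Y, paste0), W, paste0))
  unique(c(fwd, rev))
})

naive_motif_mask <- function(seq) {
  s <- toupper(seq)
  n <- nchar(s)
  mask <- logical(n)
  if (n < 4) return(mask)
  for (i in 1:(n - 3)) {
    if (substr(s, i, i + 3) %in% wrcy_kmers) mask[i:(i + 3)] <- TRUE
  }
  mask
}

# upper-tail binomial probability by term-wise enumeration
binom_tail_enum <- function(k, n, p) {
  if (k <= 0) return(1)
  if (k > n) return(0)
  sum(vapply(k:n, function(j) choose(n, j) * p^j * (1 - p)^(n - j), numeric(1)))
}

# upper-tail hypergeometric probability by term-wise enumeration:
# P(X >= k) with K marked of N, n drawn
hyper_tail_enum <- function(k, K, n, N) {
  if (k <= 0) return(1)
  hi <- min(K, n)
  if (k > hi) return(0)
  sum(vapply(k:hi, function(j)
    choose(K, j) * choose(N - K, n - j) / choose(N, n), numeric(1)))
}

random_dna <- function(n, gc = 0.5) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE,
               prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)),
        collapse = "")
}

reverse_complement <- function(s) {
  chartr("ACGT", "TGCA", paste(rev(strsplit(toupper(s), "")[[1]]), collapse = ""))
}

# minimal somatic call data.frame builder for fixtures
make_calls <- function(chrom, pos, ref, alt, sample_id = "S1",
                       call_quality = 50, alt_fraction_highqual = 0.5) {
  data.frame(sample_id = sample_id, chrom = chrom, pos = as.integer(pos),
             ref = ref, alt = alt, call_quality = call_quality,
             alt_fraction_highqual = alt_fraction_highqual,
             stringsAsFactors = FALSE)
}

# tiny single-contig genome with one window of known sequence
make_genome <- function(seqs) {
  g <- Biostrings::DNAStringSet(unlist(seqs))
  names(g) <- names(seqs)
  g
}
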