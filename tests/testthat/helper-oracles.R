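# Independent oracles used to check package computations. These deliberately
# avoid the code paths they verify (plain dictionary counting, closed-form
# likelihoods), trading speed for transparency.

# Naive canonical k-mer uniqueness: count every k-mer (and optionally its
# reverse complement) in a hash, then flag positions whose k-mer occurs once.
naive_uniqueness <- function(contigs, k, canonical = TRUE) {
  rc1 <- function(s) {
    chartr("ACGT", "TGCA", paste(rev(strsplit(s, "")[[1]]), collapse = ""))
  }
  counts <- new.env(hash = TRUE, parent = emptyenv())
  per_contig <- list()
  for (ct in names(contigs)) {
    s <- contigs[[ct]]
    n <- nchar(s)
    if (n < k) { per_contig[[ct]] <- character(0); next }
    km <- character(n - k + 1L)
    for (p in seq_len(n - k + 1L)) {
      w <- substr(s, p, p + k - 1L)
      if (canonical) { r <- rc1(w); if (r < w) w <- r }
      km[p] <- w
      counts[[w]] <- (if (is.null(counts[[w]])) 0L else counts[[w]]) + 1L
    }
    per_contig[[ct]] <- km
  }
  lapply(per_contig, function(km)
    vapply(km, function(w) counts[[w]] == 1L, logical(1), USE.NAMES = FALSE))
}

# Multinomial maximum-likelihood estimate of the positional decay
# coefficient from counts binned at fractional midpoints `mids`.
fit_decay_mle <- function(counts, mids) {
  nll <- function(l) {
    lp <- -l * mids
    -(sum(counts * lp) - sum(counts) * log(sum(exp(lp))))
  }
  stats::optimize(nll, c(-2, 8))$minimum
}

# Brute-force scan for exact occurrences of `read` (both strands) in a
# genome given as a named character vector. Returns a hit count.
brute_force_hits <- function(read, contigs) {
  rc1 <- function(s) {
    chartr("ACGT", "TGCA", paste(rev(strsplit(s, "")[[1]]), collapse = ""))
  }
  n <- 0L
  for (s in contigs) {
    for (pat in unique(c(read, rc1(read)))) {
      p <- gregexpr(pat, s, fixed = TRUE)[[1]]
      if (p[1] != -1L) n <- n + length(p)
    }
  }
  n
}

random_genome <- function(n, seed) {
  set.seed(seed)
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}
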