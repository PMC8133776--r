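#' Per-position k-mer uniqueness track
#'
#' For every k-mer start position of every contig, flags whether that k-mer
#' occurs at exactly one genomic locus. By default a k-mer and its reverse
#' complement are collapsed to one canonical entity (the lexicographic
#' minimum of the two), since an aligner reports a reverse-strand alignment
#' at the same locus; set `canonical = FALSE` for forward-strand-only
#' counting. For error-free exact matching this alignment-free computation
#' is equivalent to the alignment-based definition of mappability.
#'
#' k-mer windows containing non-ACGT characters are flagged non-unique and
#' still counted as k-mer starts, with a warning.
#'
#' @param genome A `GenomeBundle`, [Biostrings::DNAStringSet], or named
#'   character vector of contig sequences.
#' @param k k-mer length in bp (>= 2). Typical values: 25 for small RNA
#'   reads, 50 for 100 kb sliding-window analysis, 45 for 50 bp RNA-seq
#'   reads with the first 5 bases trimmed.
#' @param canonical Collapse a k-mer with its reverse complement?
#' @return A `UniquenessTrack`: list with `k`, `canonical`, and `flags`
#'   (per-contig logical vector of length `contig_length - k + 1`; length 0
#'   for contigs shorter than k).
#' @examples
#' tr <- kmer_uniqueness_track(c(chr = "AACC"), k = 2)
#' tr$flags$chr  # TRUE TRUE TRUE
#' @export
kmer_uniqueness_track <- function(genome, k, canonical = TRUE) {
  k <- as.integer(k)
  if (k < 2L) stop("k must be >= 2")
  contigs <- genome_as_character(genome)
  kmers <- list(); bad <- list()
  for (ct in names(contigs)) {
    s <- contigs[[ct]]
    n <- nchar(s)
    if (n < k) { kmers[[ct]] <- character(0); bad[[ct]] <- logical(0); next }
    np <- n - k + 1L
    km <- substring(s, seq_len(np), seq_len(np) + k - 1L)
    if (canonical) {
      rs <- revcomp_chr(s)
      rkm <- rev(substring(rs, seq_len(np), seq_len(np) + k - 1L))
      km <- ifelse(km <= rkm, km, rkm)
    }
    is_bad <- grepl("[^ACGT]", km)
    kmers[[ct]] <- km
    bad[[ct]] <- is_bad
  }
  all_km <- unlist(kmers, use.names = FALSE)
  all_bad <- unlist(bad, use.names = FALSE)
  if (any(all_bad))
    warning(sum(all_bad), " k-mer window(s) contain non-ACGT characters; ",
            "flagged non-unique")
  dup <- duplicated(all_km) | duplicated(all_km, fromLast = TRUE)
  uniq <- !dup & !all_bad
  flags <- list(); off <- 0L
  for (ct in names(contigs)) {
    np <- length(kmers[[ct]])
    flags[[ct]] <- uniq[off + seq_len(np)]
    off <- off + np
  }
  structure(list(k = k, canonical = canonical, flags = flags),
            class = "UniquenessTrack")
}

genome_as_character <- function(genome) {
  if (inherits(genome, "GenomeBundle")) genome <- genome$contigs
  if (is(genome, "DNAStringSet")) {
    out <- as.character(genome)
    if (is.null(names(out))) names(out) <- sprintf("contig%d", seq_along(out))
    return(as.list(out))
  }
  if (is.character(genome)) {
    if (is.null(names(genome)))
      names(genome) <- sprintf("contig%d", seq_along(genome))
    return(as.list(genome))
  }
  stop("genome must be a GenomeBundle, DNAStringSet, or character vector")
}

#' @export
print.UniquenessTrack <- function(x, ...) {
  nk <- sum(lengths(x$flags))
  cat("UniquenessTrack: k =", x$k,
      if (x$canonical) "(canonical)" else "(forward-only)", "-",
      nk, "k-mer starts,",
      round(100 * sum(unlist(x$flags)) / max(1L, nk), 1), "% unique\n")
  invisible(x)
}

#' Mappability score of intervals
#'
#' The mappability of an interval is the fraction of its k-mer start
#' positions (starts in `[start, end - k + 1]`) flagged unique in the track.
#' Intervals shorter than k have no k-mer starts and get a missing score.
#'
#' @param track A [kmer_uniqueness_track()].
#' @param intervals A [GenomicRanges::GRanges].
#' @return The input `GRanges` with metadata columns `score` (fraction in
#'   `[0,1]`, NA when undefined) and `n_kmer_starts`.
#' @export
interval_mappability <- function(track, intervals) {
  stopifnot(inherits(track, "UniquenessTrack"),
            is(intervals, "GRanges"))
  k <- track$k
  sc <- rep(NA_real_, length(intervals))
  nn <- integer(length(intervals))
  cts <- as.character(GenomicRanges::seqnames(intervals))
  st <- GenomicRanges::start(intervals)
  en <- GenomicRanges::end(intervals)
  for (i in seq_along(intervals)) {
    fl <- track$flags[[cts[i]]]
    if (is.null(fl))
      stop("contig ", cts[i], " not present in the uniqueness track")
    if (st[i] < 1L || en[i] > length(fl) + k - 1L)
      stop("interval ", i, " outside contig bounds")
    last <- en[i] - k + 1L
    if (last < st[i]) next  # shorter than k: missing score
    nn[i] <- last - st[i] + 1L
    sc[i] <- mean(fl[st[i]:last])
  }
  out <- intervals
  S4Vectors::mcols(out)$score <- sc
  S4Vectors::mcols(out)$n_kmer_starts <- nn
  out
}

#' Filter intervals by mappability
#'
#' @param intervals A `GRanges`.
#' @param track A [kmer_uniqueness_track()].
#' @param threshold Mappability cutoff in `[0,1]`.
#' @param mode `"greater_than"` (strict, the reading of "above 0.8" and
#'   ">0.05") or `"at_least"`.
#' @return The kept intervals (with `score` metadata). Intervals with
#'   missing scores are dropped; counts of dropped intervals are in
#'   `attr(, "n_dropped_missing")` and `attr(, "n_dropped_low")`.
#' @export
filter_by_mappability <- function(intervals, track, threshold,
                                  mode = c("greater_than", "at_least")) {
  mode <- match.arg(mode)
  if (threshold < 0 || threshold > 1) stop("threshold must be in [0,1]")
  scored <- interval_mappability(track, intervals)
  sc <- S4Vectors::mcols(scored)$score
  missing <- is.na(sc)
  pass <- !missing & (if (mode == "greater_than") sc > threshold
                      else sc >= threshold)
  out <- scored[pass]
  attr(out, "n_dropped_missing") <- sum(missing)
  attr(out, "n_dropped_low") <- sum(!missing & !pass)
  out
}
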