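#' Exact-match read alignment
#'
#' Aligns error-free reads to a genome by exact string matching: a hit is
#' every locus where the read matches the forward strand verbatim, plus
#' every locus where its reverse complement does (reported on strand `-`).
#' Matching uses [Biostrings::matchPDict()] per read-length group, so large
#' libraries align in seconds. Hits are ordered by (contig, start, strand);
#' the stored hit list is capped at `max_hits` per read while `n_hits`
#' remains exact.
#'
#' @param reads A `ReadSet` or a named [Biostrings::DNAStringSet]. Reads
#'   containing characters outside A/C/G/T, or shorter than `min_len`, are
#'   flagged unalignable (0 hits).
#' @param genome A `GenomeBundle` or [Biostrings::DNAStringSet].
#' @param max_hits Maximum hits stored per read.
#' @param min_len Minimum read length considered alignable (default 15 nt).
#' @return An object of class `AlignmentRecords`: list with `read_id`,
#'   `n_hits` (named integer, exact), `width` (named integer), `hits`
#'   (data.frame: read_id, contig, start, end, strand; 1-based closed
#'   coordinates of the match on the forward strand), and `unalignable`
#'   (character vector of read ids).
#' @export
exact_align <- function(reads, genome, max_hits = 100L, min_len = 15L) {
  seqs <- if (inherits(reads, "ReadSet")) reads$reads else reads
  stopifnot(is(seqs, "DNAStringSet"))
  if (is.null(names(seqs))) names(seqs) <- sprintf("q%06d", seq_along(seqs))
  contigs <- if (inherits(genome, "GenomeBundle")) genome$contigs else genome
  stopifnot(is(contigs, "DNAStringSet"))
  ids <- names(seqs)
  w <- Biostrings::width(seqs)
  has_bad <- Biostrings::alphabetFrequency(seqs, baseOnly = TRUE)[, "other",
                                                                  drop = TRUE]
  unalignable <- ids[w < min_len | has_bad > 0L]
  ok <- setdiff(ids, unalignable)

  hit_parts <- list()
  if (length(ok) > 0L) {
    sub <- seqs[ok]
    for (wd in unique(Biostrings::width(sub))) {
      grp <- sub[Biostrings::width(sub) == wd]
      pd_f <- Biostrings::PDict(grp)
      pd_r <- Biostrings::PDict(Biostrings::reverseComplement(grp))
      for (ct in names(contigs)) {
        subj <- contigs[[ct]]
        if (length(subj) < wd) next
        for (strand in c("+", "-")) {
          pd <- if (strand == "+") pd_f else pd_r
          m <- Biostrings::matchPDict(pd, subj)
          cnt <- S4Vectors::elementNROWS(m)
          if (sum(cnt) == 0L) next
          st <- unlist(Biostrings::startIndex(m), use.names = FALSE)
          hit_parts[[length(hit_parts) + 1L]] <- data.frame(
            read_id = rep(names(grp), cnt), contig = ct,
            start = st, end = st + wd - 1L, strand = strand,
            stringsAsFactors = FALSE)
        }
      }
    }
  }
  hits <- if (length(hit_parts)) do.call(rbind, hit_parts) else
    data.frame(read_id = character(0), contig = character(0),
               start = integer(0), end = integer(0), strand = character(0))
  if (nrow(hits)) {
    hits <- hits[order(hits$read_id, hits$contig, hits$start, hits$strand), ,
                 drop = FALSE]
    rownames(hits) <- NULL
  }
  n_hits <- stats::setNames(integer(length(ids)), ids)
  if (nrow(hits)) {
    tab <- table(hits$read_id)
    n_hits[names(tab)] <- as.integer(tab)
    # cap stored hits, keeping n_hits exact
    within <- stats::ave(seq_len(nrow(hits)), hits$read_id,
                         FUN = seq_along)
    hits <- hits[within <= max_hits, , drop = FALSE]
  }
  structure(list(read_id = ids, n_hits = n_hits,
                 width = stats::setNames(w, ids), hits = hits,
                 unalignable = unalignable, max_hits = as.integer(max_hits)),
            class = "AlignmentRecords")
}

#' @export
print.AlignmentRecords <- function(x, ...) {
  cat("AlignmentRecords:", length(x$read_id), "reads;",
      sum(x$n_hits == 1L), "unique,", sum(x$n_hits > 1L), "multimapping,",
      sum(x$n_hits == 0L), "unmapped (", length(x$unalignable),
      "unalignable )\n")
  invisible(x)
}

#' Randomly assign multimapping reads to one location
#'
#' Each read with at least one hit is assigned one of its hits uniformly at
#' random with a seeded generator (mirroring an aligner run with random
#' multimapper placement and one reported alignment per read); uniquely
#' mapping reads always receive their only hit. Reads with zero hits are
#' left unassigned and tallied.
#'
#' @param al An `AlignmentRecords` object from [exact_align()].
#' @param seed Integer seed; identical inputs and seed give identical
#'   assignments.
#' @return A data.frame of assigned alignments (one row per mapped read):
#'   read_id, contig, start, end, strand, width, n_hits; the number of
#'   unmapped reads is in `attr(, "n_unassigned")`.
#' @export
assign_multimappers <- function(al, seed = 1L) {
  stopifnot(inherits(al, "AlignmentRecords"))
  hits <- al$hits
  if (nrow(hits) == 0L) {
    out <- data.frame(read_id = character(0), contig = character(0),
                      start = integer(0), end = integer(0),
                      strand = character(0), width = integer(0),
                      n_hits = integer(0))
    attr(out, "n_unassigned") <- sum(al$n_hits == 0L)
    return(out)
  }
  # hits are sorted by read_id; pick a per-read offset into its block
  with_substream(seed, "assign_multimappers", {
    rid <- hits$read_id
    stored <- as.integer(table(rid)[unique(rid)])
    first <- c(1L, cumsum(stored)[-length(stored)] + 1L)
    pick <- first + floor(stats::runif(length(stored)) * stored)
    out <- hits[pick, , drop = FALSE]
    out$width <- al$width[out$read_id]
    out$n_hits <- al$n_hits[out$read_id]
    rownames(out) <- NULL
    attr(out, "n_unassigned") <- sum(al$n_hits == 0L)
    out
  })
}

# Assigned alignments as a GRanges (internal convenience).
assigned_granges <- function(assigned) {
  gr <- GenomicRanges::GRanges(assigned$contig,
                               IRanges::IRanges(assigned$start,
                                                assigned$end),
                               strand = assigned$strand)
  S4Vectors::mcols(gr)$read_id <- assigned$read_id
  S4Vectors::mcols(gr)$n_hits <- assigned$n_hits
  gr
}
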