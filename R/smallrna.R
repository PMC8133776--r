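#' Clip the 3' adapter from raw small RNA reads
#'
#' Truncates each read at the leftmost exact occurrence of the adapter's
#' first `min_adapter_match` nucleotides. Reads in which the adapter is not
#' found are kept whole. Clipped reads shorter than `min_clipped_len` are
#' discarded with reason `no_min_length` (the protocol's insert plus two
#' 4 nt randomized flanks must reach 23 bp).
#'
#' @param reads Character vector (named) of raw read sequences, or a
#'   `ReadSet` of kind `srna_raw`.
#' @param adapter 3' adapter sequence.
#' @param min_clipped_len Minimum clipped length to retain (default 23).
#' @param min_adapter_match Length of the adapter prefix that must match
#'   exactly (default 7).
#' @return A list with `kept` (named character vector of clipped sequences)
#'   and `discarded` (data.frame: id, reason).
#' @export
clip_adapter <- function(reads, adapter = default_srna_adapter(),
                         min_clipped_len = 23L, min_adapter_match = 7L) {
  if (inherits(reads, "ReadSet")) reads <- as.character(reads$reads)
  if (is.null(names(reads))) names(reads) <- sprintf("q%06d",
                                                     seq_along(reads))
  if (nchar(adapter) < min_adapter_match)
    stop("adapter shorter than min_adapter_match")
  probe <- substring(adapter, 1L, min_adapter_match)
  pos <- regexpr(probe, reads, fixed = TRUE)
  clipped <- ifelse(pos > 0L, substring(reads, 1L, pos - 1L), reads)
  names(clipped) <- names(reads)
  short <- nchar(clipped) < min_clipped_len
  list(kept = clipped[!short],
       discarded = data.frame(id = names(clipped)[short],
                              reason = rep("no_min_length", sum(short)),
                              stringsAsFactors = FALSE))
}

#' Trim the randomized 4 nt flanks
#'
#' Removes the first and last `n` bases of each clipped read, recording them
#' as the 5' and 3' randomized flanks; the remainder is the insert. Reads
#' shorter than `2n + 1` cannot yield an insert and are discarded with
#' reason `no_min_length`.
#'
#' @param clipped Named character vector of adapter-clipped sequences.
#' @param n Number of randomized bases on each end (default 4).
#' @return A list with `inserts` (data.frame: id, insert, umi5, umi3) and
#'   `discarded` (data.frame: id, reason).
#' @export
trim_random_ends <- function(clipped, n = 4L) {
  if (is.null(names(clipped))) names(clipped) <- sprintf("q%06d",
                                                         seq_along(clipped))
  len <- nchar(clipped)
  ok <- len >= 2L * n + 1L
  ins <- data.frame(
    id = names(clipped)[ok],
    insert = substring(clipped[ok], n + 1L, len[ok] - n),
    umi5 = substring(clipped[ok], 1L, n),
    umi3 = substring(clipped[ok], len[ok] - n + 1L, len[ok]),
    stringsAsFactors = FALSE)
  list(inserts = ins,
       discarded = data.frame(id = names(clipped)[!ok],
                              reason = rep("no_min_length", sum(!ok)),
                              stringsAsFactors = FALSE))
}

#' Remove rRNA/tRNA contaminant inserts
#'
#' Aligns inserts with [exact_align()] and discards (reason `contaminant`)
#' those whose hits fall entirely within blacklist loci. An insert with at
#' least one hit outside the blacklist is retained (conservative policy for
#' multimappers); inserts with no hits are retained here and handled by the
#' aligner's unalignable flag downstream.
#'
#' @param inserts data.frame from [trim_random_ends()] (columns id, insert).
#' @param blacklist A `GRanges` of rRNA/tRNA loci.
#' @param genome A `GenomeBundle` or `DNAStringSet`.
#' @param al Optional precomputed `AlignmentRecords` for these inserts.
#' @return A list with `kept` (the surviving rows of `inserts`), `discarded`
#'   (data.frame: id, reason), and `alignments` (the `AlignmentRecords`).
#' @export
remove_contaminants <- function(inserts, blacklist, genome, al = NULL) {
  if (is.null(al)) {
    seqs <- Biostrings::DNAStringSet(stats::setNames(inserts$insert,
                                                     inserts$id))
    al <- exact_align(seqs, genome)
  }
  hits <- al$hits
  contaminated <- character(0)
  if (nrow(hits) > 0L && length(blacklist) > 0L) {
    hg <- GenomicRanges::GRanges(hits$contig,
                                 IRanges::IRanges(hits$start, hits$end))
    inside <- IRanges::overlapsAny(hg, blacklist, type = "within",
                                   ignore.strand = TRUE)
    all_inside <- tapply(inside, hits$read_id, all)
    contaminated <- names(all_inside)[all_inside]
  }
  drop <- inserts$id %in% contaminated
  list(kept = inserts[!drop, , drop = FALSE],
       discarded = data.frame(id = inserts$id[drop],
                              reason = rep("contaminant", sum(drop)),
                              stringsAsFactors = FALSE),
       alignments = al)
}

#' Classify assigned small RNA reads
#'
#' Assigns a length class (`siRNA_21` for exactly 21 nt inserts,
#' `piRNA_23_29` for inserts of 23-29 nt, else `other`) and a feature class
#' from the annotation overlapping the assigned locus, with precedence
#' miRNA locus > TE insertion > cluster > gene 3'UTR > none. Orientation is
#' `sense` when the read strand equals the feature strand, `antisense`
#' otherwise, and `n/a` for reads without a feature.
#'
#' @param assigned data.frame of assigned alignments
#'   (from [assign_multimappers()]).
#' @param annotations List with stranded `GRanges` elements `mirna_loci`,
#'   `te_insertions`, `cluster`, `utr3` (any may be empty); a `GenomeBundle`
#'   works directly.
#' @param pirna_range Length window for the piRNA class (default 23-29 nt).
#' @return data.frame: read_id, contig, start, end, strand, insert_len,
#'   length_class, feature_class, feature_id, orientation.
#' @export
classify_small_rnas <- function(assigned, annotations,
                                pirna_range = c(23L, 29L)) {
  ann <- annotations
  n <- nrow(assigned)
  len <- as.integer(assigned$width)
  length_class <- rep("other", n)
  length_class[len == 21L] <- "siRNA_21"
  length_class[len >= pirna_range[1] & len <= pirna_range[2]] <-
    "piRNA_23_29"
  reads_gr <- assigned_granges(assigned)

  feature_class <- rep("none", n)
  feature_id <- rep(NA_character_, n)
  feat_strand <- rep(NA_character_, n)
  layers <- list(
    gene_3UTR = ann$utr3,
    cluster = ann$cluster,
    TE = ann$te_insertions,
    miRNA_locus = ann$mirna_loci)
  # apply from lowest to highest precedence so later layers overwrite
  for (nm in names(layers)) {
    feats <- layers[[nm]]
    if (is.null(feats) || length(feats) == 0L) next
    ov <- GenomicRanges::findOverlaps(reads_gr, feats,
                                      ignore.strand = TRUE)
    qh <- S4Vectors::queryHits(ov); sh <- S4Vectors::subjectHits(ov)
    keep <- !duplicated(qh)
    qh <- qh[keep]; sh <- sh[keep]
    feature_class[qh] <- nm
    ids <- names(feats)
    if (is.null(ids)) {
      idcol <- intersect(c("copy_id", "id", "gene_id"),
                         names(S4Vectors::mcols(feats)))
      ids <- if (length(idcol)) S4Vectors::mcols(feats)[[idcol[1]]] else
        as.character(seq_along(feats))
    }
    feature_id[qh] <- ids[sh]
    feat_strand[qh] <- as.character(GenomicRanges::strand(feats))[sh]
  }
  orientation <- ifelse(feature_class == "none", "n/a",
                        ifelse(assigned$strand == feat_strand,
                               "sense", "antisense"))
  data.frame(read_id = assigned$read_id, contig = assigned$contig,
             start = assigned$start, end = assigned$end,
             strand = assigned$strand, n_hits = assigned$n_hits,
             insert_len = len,
             length_class = length_class, feature_class = feature_class,
             feature_id = feature_id, orientation = orientation,
             stringsAsFactors = FALSE)
}

#' Summarise a classified library into counts
#'
#' @param classified data.frame from [classify_small_rnas()].
#' @return A list of class `LibraryCounts`: `total_aligned`, `mirna_reads`,
#'   and `by_feature` (data.frame: feature_class, orientation, length_class,
#'   n).
#' @export
library_counts <- function(classified) {
  by_feature <- stats::aggregate(
    list(n = rep(1L, nrow(classified))),
    classified[, c("feature_class", "orientation", "length_class")],
    FUN = sum)
  structure(list(
    total_aligned = nrow(classified),
    mirna_reads = sum(classified$feature_class == "miRNA_locus"),
    by_feature = by_feature), class = "LibraryCounts")
}

#' miRNA-anchored normalisation of small RNA counts
#'
#' Small RNA libraries lack a stable total because piRNA content itself
#' changes between conditions; counts are therefore scaled so that miRNA
#' reads (assumed unaffected) are equalised across libraries, anchored so
#' that the control library's values equal plain rpm. For library *i*:
#' `normalized(x) = x * (1e6 / total_control) * (mirna_control / mirna_i)`.
#'
#' @param counts Named list of `LibraryCounts` (or any list with elements
#'   `total_aligned` and `mirna_reads`), one per library.
#' @param control Name of the control library.
#' @return A named numeric vector of per-library scaling factors: multiply a
#'   library's raw counts by its factor to get normalized values.
#' @export
mirna_norm_factors <- function(counts, control) {
  if (!control %in% names(counts)) stop("control library not found")
  mir <- vapply(counts, function(x) as.numeric(x$mirna_reads), numeric(1))
  if (any(mir <= 0))
    stop("normalisation error: zero miRNA reads in library ",
         paste(names(counts)[mir <= 0], collapse = ", "))
  tot_c <- as.numeric(counts[[control]]$total_aligned)
  if (tot_c <= 0) stop("normalisation error: empty control library")
  1e6 / tot_c * (mir[[control]] / mir)
}

#' @rdname mirna_norm_factors
#' @param x Numeric vector of raw counts from one library.
#' @param library Name of the library `x` belongs to.
#' @param counts,control As above.
#' @return `mirna_normalize()`: `x` scaled to normalized units.
#' @export
mirna_normalize <- function(x, library, counts, control) {
  f <- mirna_norm_factors(counts, control)
  if (!library %in% names(f)) stop("unknown library: ", library)
  x * f[[library]]
}

#' Run the full small RNA processing chain
#'
#' Convenience wrapper: adapter clipping, flank trimming, contaminant
#' removal, exact alignment, seeded multimapper assignment and
#' classification, with full bookkeeping (every input read is accounted for
#' as retained or discarded with a reason).
#'
#' @param readset A `ReadSet` of kind `srna_raw`.
#' @param bundle A `GenomeBundle`.
#' @param seed Seed for multimapper assignment.
#' @param adapter,min_clipped_len,umi_n Processing parameters.
#' @return List with `classified` (data.frame), `counts` (`LibraryCounts`),
#'   `assigned`, `alignments`, and `ledger` (data.frame: id, fate).
#' @export
process_small_rna_library <- function(readset, bundle, seed = 1L,
                                      adapter = readset$adapter,
                                      min_clipped_len = 23L, umi_n = 4L) {
  stopifnot(inherits(readset, "ReadSet"),
            identical(readset$library_kind, "srna_raw"))
  cl <- clip_adapter(readset, adapter, min_clipped_len = min_clipped_len)
  tr <- trim_random_ends(cl$kept, n = umi_n)
  rc <- remove_contaminants(tr$inserts, bundle$blacklist_loci, bundle)
  al <- rc$alignments
  keep_ids <- rc$kept$id
  unal <- intersect(keep_ids, union(al$unalignable,
                                    names(al$n_hits)[al$n_hits == 0L]))
  mapped_ids <- setdiff(keep_ids, unal)
  assigned <- assign_multimappers(al, seed = seed)
  assigned <- assigned[assigned$read_id %in% mapped_ids, , drop = FALSE]
  classified <- classify_small_rnas(assigned, bundle)
  ledger <- rbind(
    cl$discarded, tr$discarded, rc$discarded,
    data.frame(id = unal, reason = rep("unalignable", length(unal)),
               stringsAsFactors = FALSE),
    data.frame(id = mapped_ids, reason = rep("retained", length(mapped_ids)),
               stringsAsFactors = FALSE))
  names(ledger) <- c("id", "fate")
  list(classified = classified, counts = library_counts(classified),
       assigned = assigned, alignments = al, ledger = ledger)
}
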