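#' Expression profile for the cluster RNA-seq simulator
#'
#' The expected read-start rate at fractional position `x` (0 at the
#' cluster's 5' end, 1 at its 3' end, measured along the transcribed strand)
#' is `base_rate * scale * exp(-decay * x)`. `decay = 0, scale = 1`
#' reproduces the control condition; `decay > 0` gives a 5'-to-3'
#' destabilisation gradient (the nucleoporin-knockdown-like condition);
#' `decay = 0, scale = 2` gives uniform up-regulation (the
#' processing-blocked, zuc-knockdown-like condition).
#'
#' @param base_rate Expected read starts per bp over the cluster in the
#'   control condition (relative weight against `gene_rates`).
#' @param scale Multiplicative factor applied uniformly along the cluster.
#' @param decay Positional decay coefficient per unit fractional position.
#' @param gene_rates Named numeric: expected relative read weight per gene
#'   (names must match gene ids of the bundle). NULL = no gene reads.
#' @return An `expression_profile` object.
#' @export
expression_profile <- function(base_rate = 0.02, scale = 1, decay = 0,
                               gene_rates = NULL) {
  stopifnot(base_rate >= 0, scale >= 0)
  structure(list(base_rate = base_rate, scale = scale, decay = decay,
                 gene_rates = gene_rates),
            class = "expression_profile")
}

#' Simulate stranded cluster RNA-seq reads
#'
#' Draws error-free reads whose 5' start positions along the cluster follow
#' the positional rate of an [expression_profile()]; reads are faithful to
#' the cluster's transcribed strand. Gene reads are drawn uniformly within
#' each gene on the gene's strand. Total depth is split between the cluster
#' and the genes proportionally to their expected rates (multinomial).
#'
#' @param bundle A `GenomeBundle`.
#' @param profile An [expression_profile()].
#' @param read_length Read length in bp (must not exceed the cluster length).
#' @param depth Total number of reads to draw; 0 gives an empty set.
#' @param seed Integer seed.
#' @return A `ReadSet`: list with `reads` (named [Biostrings::DNAStringSet]),
#'   `truth` (data.frame: id, contig, start, end, strand, class, frac_pos),
#'   `library_kind = "rnaseq"`, `read_length`.
#' @export
simulate_cluster_rnaseq <- function(bundle, profile, read_length = 50L,
                                    depth, seed = 1L) {
  stopifnot(inherits(bundle, "GenomeBundle"),
            inherits(profile, "expression_profile"))
  read_length <- as.integer(read_length)
  Lc <- GenomicRanges::width(bundle$cluster)
  if (read_length > Lc) stop("read_length exceeds cluster_length")
  depth <- as.integer(depth)

  with_substream(seed, "simulate_cluster_rnaseq", {
    lam <- profile$decay
    mean_decay <- if (lam == 0) 1 else (1 - exp(-lam)) / lam
    w_cluster <- profile$base_rate * profile$scale * Lc * mean_decay
    grates <- profile$gene_rates
    if (!is.null(grates) && length(grates) > 0L &&
        !all(names(grates) %in% bundle$genes$gene_id))
      stop("gene_rates names must match gene ids in the bundle")
    weights <- c(cluster = w_cluster, grates)
    if (depth == 0L || sum(weights) == 0) {
      return(structure(list(reads = Biostrings::DNAStringSet(),
                            truth = data.frame(),
                            library_kind = "rnaseq",
                            read_length = read_length),
                       class = "ReadSet"))
    }
    alloc <- as.vector(stats::rmultinom(1L, depth, weights))
    names(alloc) <- names(weights)

    contig <- as.character(GenomicRanges::seqnames(bundle$cluster))
    cstart <- GenomicRanges::start(bundle$cluster)
    cstrand <- as.character(GenomicRanges::strand(bundle$cluster))
    genome_chr <- as.character(bundle$contigs[[contig]])

    rows <- list()
    ## cluster reads: inverse-CDF sampling of the truncated exponential
    nc <- alloc[["cluster"]]
    if (nc > 0L) {
      u <- stats::runif(nc)
      x <- if (lam == 0) u else -log(1 - u * (1 - exp(-lam))) / lam
      # x is the fractional 5' start along the transcript
      offs <- floor(x * (Lc - read_length)) # 0 .. Lc - read_length
      if (cstrand == "+") {
        starts <- cstart + as.integer(offs)
      } else {
        starts <- GenomicRanges::end(bundle$cluster) - as.integer(offs) -
          read_length + 1L
      }
      rows[[length(rows) + 1L]] <- data.frame(
        contig = contig, start = starts, end = starts + read_length - 1L,
        strand = cstrand, class = "cluster", frac_pos = x,
        stringsAsFactors = FALSE)
    }
    ## gene reads
    for (g in setdiff(names(alloc), "cluster")) {
      ng <- alloc[[g]]
      if (ng == 0L) next
      gi <- bundle$genes[bundle$genes$gene_id == g]
      gs <- GenomicRanges::start(gi); ge <- GenomicRanges::end(gi)
      starts <- gs + sample.int(ge - gs - read_length + 2L, ng,
                                replace = TRUE) - 1L
      rows[[length(rows) + 1L]] <- data.frame(
        contig = contig, start = starts, end = starts + read_length - 1L,
        strand = as.character(GenomicRanges::strand(gi)), class = g,
        frac_pos = NA_real_, stringsAsFactors = FALSE)
    }
    truth <- do.call(rbind, rows)
    truth$id <- sprintf("r%07d", seq_len(nrow(truth)))
    seqs <- substring(genome_chr, truth$start, truth$end)
    neg <- truth$strand == "-"
    if (any(neg)) seqs[neg] <- revcomp_chr(seqs[neg])
    reads <- Biostrings::DNAStringSet(stats::setNames(seqs, truth$id))
    structure(list(reads = reads,
                   truth = truth[, c("id", "contig", "start", "end",
                                     "strand", "class", "frac_pos")],
                   library_kind = "rnaseq", read_length = read_length),
              class = "ReadSet")
  })
}

#' Default small RNA 3' adapter sequence
#'
#' The standard TruSeq small RNA 3' adapter used for library construction.
#' @return A character scalar.
#' @export
default_srna_adapter <- function() "AGATCGGAAGAGCACACGTCTGAACTCCAGTCA"

#' Simulate a raw small RNA library
#'
#' Emulates a library protocol whose 5' and 3' adapters each carry four
#' randomized nucleotides at their insert-facing ends: every raw read is
#' `4 random nt + insert + 4 random nt + 3' adapter`, truncated at the read
#' length. Insert classes: `mirna` (from miRNA loci, on the locus strand),
#' `sirna21` (exactly 21 nt from dispersed TE insertions, either strand),
#' `pirna_cluster` (23-29 nt from the cluster's transcribed strand, hence
#' genomically antisense to antisense-embedded TE fragments), and
#' `pirna_other` (23-29 nt antisense to dispersed TE insertions).
#'
#' @param bundle A `GenomeBundle`.
#' @param composition Named integer vector with (a subset of) the names
#'   `mirna`, `sirna21`, `pirna_cluster`, `pirna_other`; unknown names are an
#'   error.
#' @param adapter 3' adapter sequence (>= 10 nt).
#' @param seed Integer seed.
#' @param read_length Sequencer read length; raw reads longer than this are
#'   truncated (the usual source of partial adapters).
#' @param pirna_len_range,mirna_len_range Insert length ranges.
#' @return A `ReadSet` with `library_kind = "srna_raw"`; `truth` records
#'   class, insert genomic coordinates, strand, insert length and the two
#'   randomized flanks.
#' @export
simulate_small_rna_library <- function(bundle, composition,
                                       adapter = default_srna_adapter(),
                                       seed = 1L, read_length = 50L,
                                       pirna_len_range = c(23L, 29L),
                                       mirna_len_range = c(21L, 23L)) {
  stopifnot(inherits(bundle, "GenomeBundle"))
  known <- c("mirna", "sirna21", "pirna_cluster", "pirna_other")
  if (is.null(names(composition)) || !all(names(composition) %in% known))
    stop("unknown read class in composition; known classes: ",
         paste(known, collapse = ", "))
  if (nchar(adapter) < 10L) stop("adapter must be at least 10 nt")
  comp <- stats::setNames(rep(0L, length(known)), known)
  comp[names(composition)] <- as.integer(composition)

  with_substream(seed, "simulate_small_rna_library", {
    contig <- as.character(GenomicRanges::seqnames(bundle$cluster))
    genome_chr <- as.character(bundle$contigs[[contig]])
    cstrand <- as.character(GenomicRanges::strand(bundle$cluster))

    draw_from <- function(gr, n, len_range, strand_rule) {
      # strand_rule: "feature" (on feature strand), "anti" (opposite),
      # "either", or "cluster" (the cluster's transcribed strand)
      if (n == 0L) return(NULL)
      if (length(gr) == 0L) stop("no loci available for requested class")
      idx <- sample.int(length(gr), n, replace = TRUE)
      lens <- len_range[1] +
        sample.int(len_range[2] - len_range[1] + 1L, n, replace = TRUE) - 1L
      fs <- GenomicRanges::start(gr)[idx]
      fe <- GenomicRanges::end(gr)[idx]
      fw <- fe - fs + 1L
      if (any(lens > fw)) lens <- pmin(lens, fw)
      starts <- fs + floor(stats::runif(n) * (fw - lens + 1))
      fstrand <- as.character(GenomicRanges::strand(gr))[idx]
      strand <- switch(strand_rule,
        feature = fstrand,
        anti = ifelse(fstrand == "+", "-", "+"),
        either = sample(c("+", "-"), n, replace = TRUE),
        cluster = rep(cstrand, n))
      data.frame(contig = contig, start = as.integer(starts),
                 end = as.integer(starts + lens - 1L), strand = strand,
                 insert_len = lens, stringsAsFactors = FALSE)
    }

    dispersed <- bundle$te_insertions[!bundle$te_insertions$in_cluster]
    parts <- list(
      mirna = draw_from(bundle$mirna_loci, comp[["mirna"]],
                        mirna_len_range, "feature"),
      sirna21 = draw_from(dispersed, comp[["sirna21"]],
                          c(21L, 21L), "either"),
      pirna_cluster = draw_from(bundle$cluster, comp[["pirna_cluster"]],
                                pirna_len_range, "cluster"),
      pirna_other = draw_from(dispersed, comp[["pirna_other"]],
                              pirna_len_range, "anti"))
    truth <- do.call(rbind, c(Map(function(df, cl) {
      if (is.null(df)) return(NULL)
      df$class <- cl
      df
    }, parts, names(parts)), list(make.row.names = FALSE)))
    if (is.null(truth) || nrow(truth) == 0L) {
      return(structure(list(reads = Biostrings::DNAStringSet(),
                            truth = data.frame(), adapter = adapter,
                            library_kind = "srna_raw",
                            read_length = as.integer(read_length)),
                       class = "ReadSet"))
    }
    # shuffle so class blocks are not contiguous in the FASTQ
    truth <- truth[sample.int(nrow(truth)), , drop = FALSE]
    truth$id <- sprintf("s%06d", seq_len(nrow(truth)))

    inserts <- substring(genome_chr, truth$start, truth$end)
    neg <- truth$strand == "-"
    if (any(neg)) inserts[neg] <- revcomp_chr(inserts[neg])
    n <- nrow(truth)
    rand4 <- function(n) vapply(seq_len(n), function(i)
      paste(sample(c("A", "C", "G", "T"), 4L, replace = TRUE),
            collapse = ""), character(1))
    truth$umi5 <- rand4(n)
    truth$umi3 <- rand4(n)
    raw <- substring(paste0(truth$umi5, inserts, truth$umi3, adapter),
                     1L, read_length)
    reads <- Biostrings::DNAStringSet(stats::setNames(raw, truth$id))
    structure(list(reads = reads,
                   truth = truth[, c("id", "class", "contig", "start", "end",
                                     "strand", "insert_len", "umi5", "umi3")],
                   adapter = adapter, library_kind = "srna_raw",
                   read_length = as.integer(read_length)),
              class = "ReadSet")
  })
}

#' @export
print.ReadSet <- function(x, ...) {
  cat("ReadSet (", x$library_kind, "): ", length(x$reads), " reads\n",
      sep = "")
  invisible(x)
}
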