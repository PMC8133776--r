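#' Reference coordinates of the Drosophila uni-strand piRNA clusters
#'
#' The dm6 coordinates (1-based, inclusive) of the two somatic uni-strand
#' piRNA clusters: *flamenco* (chrX:21,631,891-22,282,863, transcribed from
#' the + strand) and *20A* (chrX:21,520,428-21,556,793). These are the
#' intervals used for real-genome window arithmetic; all toy analyses use
#' the simulated bundle's own cluster instead.
#'
#' @param which `"flam"` or `"cluster20A"`.
#' @return A length-1 [GenomicRanges::GRanges].
#' @examples
#' GenomicRanges::width(flam_region())  # 650973 bp, i.e. ~650 kb
#' @export
flam_region <- function(which = c("flam", "cluster20A")) {
  which <- match.arg(which)
  switch(which,
    flam = GenomicRanges::GRanges(
      "chrX", IRanges::IRanges(21631891L, 22282863L), strand = "+"),
    cluster20A = GenomicRanges::GRanges(
      "chrX", IRanges::IRanges(21520428L, 21556793L), strand = "+"))
}

#' Write a genome bundle to disk
#'
#' Writes the contigs as FASTA, the annotation sets as BED6 (0-based
#' half-open, converted at this boundary) and the truth ledger as TSV.
#'
#' @param bundle A `GenomeBundle`.
#' @param dir Output directory (created if missing).
#' @return Invisibly, the named vector of written paths.
#' @export
write_genome_bundle <- function(bundle, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- c(genome = file.path(dir, "genome.fa"),
             cluster = file.path(dir, "cluster.bed"),
             te_insertions = file.path(dir, "te_insertions.bed"),
             genes = file.path(dir, "genes.bed"),
             mirna = file.path(dir, "mirna_loci.bed"),
             blacklist = file.path(dir, "blacklist.bed"),
             truth = file.path(dir, "truth.tsv"))
  Biostrings::writeXStringSet(bundle$contigs, paths[["genome"]])
  write_bed6(bundle$cluster, paths[["cluster"]], name = "cluster")
  write_bed6(bundle$te_insertions, paths[["te_insertions"]],
             name = bundle$te_insertions$copy_id)
  write_bed6(bundle$genes, paths[["genes"]], name = bundle$genes$gene_id)
  write_bed6(bundle$mirna_loci, paths[["mirna"]], name = bundle$mirna_loci$id)
  write_bed6(bundle$blacklist_loci, paths[["blacklist"]],
             name = bundle$blacklist_loci$id)
  utils::write.table(bundle$truth, paths[["truth"]], sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(paths)
}

#' Write intervals as BED6
#'
#' Internal coordinates are 1-based closed `GRanges`; BED output is 0-based
#' half-open per the format definition.
#'
#' @param gr A `GRanges`.
#' @param path Output path.
#' @param name,score BED name and score columns (recycled).
#' @return Invisibly, `path`.
#' @export
write_bed6 <- function(gr, path, name = ".", score = 0L) {
  df <- data.frame(chrom = as.character(GenomicRanges::seqnames(gr)),
                   start = GenomicRanges::start(gr) - 1L,
                   end = GenomicRanges::end(gr),
                   name = if (length(gr)) rep_len(name, length(gr))
                          else character(0),
                   score = if (length(gr)) rep_len(score, length(gr))
                           else integer(0),
                   strand = as.character(GenomicRanges::strand(gr)))
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a BED6 file as GRanges
#'
#' @param path A BED6 file (0-based half-open; converted to 1-based closed).
#' @return A stranded `GRanges` with `name` metadata.
#' @export
read_bed6 <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = FALSE,
                          stringsAsFactors = FALSE)
  gr <- GenomicRanges::GRanges(df[[1]],
                               IRanges::IRanges(df[[2]] + 1L, df[[3]]),
                               strand = if (ncol(df) >= 6) df[[6]] else "*")
  if (ncol(df) >= 4) S4Vectors::mcols(gr)$name <- df[[4]]
  gr
}

#' Write a read set as FASTQ
#'
#' Qualities are emitted as a constant high value, since the simulator
#' produces error-free reads.
#'
#' @param readset A `ReadSet`.
#' @param path Output path (uncompressed FASTQ).
#' @return Invisibly, `path`.
#' @export
write_fastq <- function(readset, path) {
  Biostrings::writeXStringSet(
    readset$reads, path, format = "fastq",
    qualities = Biostrings::BStringSet(
      vapply(Biostrings::width(readset$reads),
             function(w) paste(rep("I", w), collapse = ""), character(1))))
  invisible(path)
}

#' Read a FASTQ file as a ReadSet
#'
#' @param path FASTQ path.
#' @param library_kind Tag for the resulting set.
#' @return A `ReadSet` without a truth ledger.
#' @export
read_fastq <- function(path, library_kind = "rnaseq") {
  seqs <- Biostrings::readDNAStringSet(path, format = "fastq")
  names(seqs) <- sub("\\s.*$", "", names(seqs))
  structure(list(reads = seqs, truth = NULL, library_kind = library_kind,
                 read_length = if (length(seqs))
                   max(Biostrings::width(seqs)) else NA_integer_),
            class = "ReadSet")
}

#' Export a uniqueness track as bedGraph
#'
#' One line per k-mer start with value 1 (unique) or 0.
#'
#' @param track A [kmer_uniqueness_track()].
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_track_bedgraph <- function(track, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("track type=bedGraph name=kmer_uniqueness_k%d",
                     track$k), con)
  for (ct in names(track$flags)) {
    fl <- track$flags[[ct]]
    if (!length(fl)) next
    r <- rle(as.integer(fl))
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths  # 0-based
    writeLines(sprintf("%s\t%d\t%d\t%d", ct, starts, ends, r$values), con)
  }
  invisible(path)
}
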