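#' Simulation parameters for the toy genome
#'
#' Bundles the knobs of [simulate_genome()] with validation. Defaults give a
#' desk-scale caricature of the *flamenco* setting: a 500 kb contig carrying a
#' 60 kb uni-strand piRNA cluster assembled from fragments of transposon
#' (TE) families that also have full-length copies dispersed elsewhere,
#' creating genuine multimapping structure.
#'
#' @param genome_length Total contig length in bp.
#' @param n_te_families Number of TE families to engineer.
#' @param te_length Length of each family consensus in bp.
#' @param cluster_length Length of the uni-strand cluster in bp.
#' @param n_dispersed_insertions_per_family Full-length copies of each family
#'   placed outside the cluster. The first copy per family is placed within
#'   -10 kb/+15 kb of a gene's TSS on the gene's strand and flagged in the
#'   truth ledger.
#' @param n_cluster_fragments_per_family Fragments of each family embedded in
#'   the cluster.
#' @param n_genes,gene_length Protein-coding gene stand-ins (with TSS,
#'   strand, and a 300 bp 3'UTR annotation).
#' @param n_mirna_loci,mirna_length miRNA locus stand-ins (unique sequence).
#' @param n_blacklist_loci,blacklist_length rRNA/tRNA stand-ins used as the
#'   contaminant blacklist.
#' @param gc_fraction GC content of all random sequence, in `[0, 1]`.
#' @param antisense_fraction Probability that a cluster-embedded TE fragment
#'   is antisense to the TE consensus (i.e. silencing-competent orientation).
#' @param seed Integer root seed; identical parameters give byte-identical
#'   output.
#' @return An object of class `sim_params` (a validated list).
#' @export
sim_params <- function(genome_length = 500000L,
                       n_te_families = 4L,
                       te_length = 2000L,
                       cluster_length = 60000L,
                       n_dispersed_insertions_per_family = 4L,
                       n_cluster_fragments_per_family = 2L,
                       n_genes = 20L,
                       gene_length = 2000L,
                       n_mirna_loci = 5L,
                       mirna_length = 80L,
                       n_blacklist_loci = 2L,
                       blacklist_length = 800L,
                       gc_fraction = 0.42,
                       antisense_fraction = 1.0,
                       seed = 1L) {
  p <- list(genome_length = as.integer(genome_length),
            n_te_families = as.integer(n_te_families),
            te_length = as.integer(te_length),
            cluster_length = as.integer(cluster_length),
            n_dispersed_insertions_per_family =
              as.integer(n_dispersed_insertions_per_family),
            n_cluster_fragments_per_family =
              as.integer(n_cluster_fragments_per_family),
            n_genes = as.integer(n_genes),
            gene_length = as.integer(gene_length),
            n_mirna_loci = as.integer(n_mirna_loci),
            mirna_length = as.integer(mirna_length),
            n_blacklist_loci = as.integer(n_blacklist_loci),
            blacklist_length = as.integer(blacklist_length),
            gc_fraction = gc_fraction,
            antisense_fraction = antisense_fraction,
            seed = as.integer(seed))
  counts <- p[c("n_te_families", "n_dispersed_insertions_per_family",
                "n_cluster_fragments_per_family", "n_genes", "n_mirna_loci",
                "n_blacklist_loci")]
  if (any(unlist(counts) < 0L)) stop("all counts must be >= 0")
  if (p$cluster_length >= p$genome_length)
    stop("cluster_length must be smaller than genome_length")
  if (p$gc_fraction < 0 || p$gc_fraction > 1)
    stop("gc_fraction must be in [0, 1]")
  if (p$antisense_fraction < 0 || p$antisense_fraction > 1)
    stop("antisense_fraction must be in [0, 1]")
  structure(p, class = "sim_params")
}

random_dna <- function(n, gc) {
  if (n == 0L) return("")
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE,
               prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)),
        collapse = "")
}

revcomp_chr <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

# Rejection-sample a non-overlapping placement of width `w` inside `region`,
# keeping `gap` bp clearance from everything already in `occupied`.
.place <- function(w, occupied, region, gap = 50L, tries = 2000L) {
  lo <- IRanges::start(region); hi <- IRanges::end(region) - w + 1L
  if (hi < lo) stop("sizing error: feature of width ", w, " does not fit")
  for (i in seq_len(tries)) {
    s <- lo + sample.int(hi - lo + 1L, 1L) - 1L
    cand <- IRanges::IRanges(s, width = w)
    if (length(occupied) == 0L ||
        !any(IRanges::overlapsAny(cand + gap, occupied)))
      return(cand)
  }
  stop("sizing error: could not place a feature of width ", w,
       " after ", tries, " attempts; requested features exceed genome_length")
}

#' Simulate a toy genome with an engineered piRNA cluster
#'
#' Builds a single random contig and engineers into it: a uni-strand piRNA
#' cluster whose sense strand carries (by default antisense) fragments of
#' each TE family; dispersed full-length insertions of every family outside
#' the cluster, one of which per family sits within -10 kb/+15 kb of a gene
#' TSS on the gene's strand (flagged in the truth ledger); genes with TSS,
#' strand and a 3'UTR annotation; miRNA loci; and rRNA/tRNA blacklist
#' stand-ins. Every engineered repeat copy is recorded in the `truth` ledger,
#' so alignment, classification and counting results can be checked exactly.
#'
#' All intervals are 1-based closed [GenomicRanges::GRanges] (converted to
#' 0-based half-open only when written as BED).
#'
#' @param params A [sim_params()] object.
#' @return A `GenomeBundle`: list with elements `contigs`
#'   ([Biostrings::DNAStringSet]), `cluster`, `te_insertions`, `genes`,
#'   `utr3`, `mirna_loci`, `blacklist_loci` (all `GRanges`), `te_consensus`
#'   (`DNAStringSet`), `truth` (data.frame ledger of repeat copies), and
#'   `params`.
#' @examples
#' b <- simulate_genome(sim_params(genome_length = 60000, cluster_length = 10000,
#'                                 n_genes = 4, seed = 7))
#' b$cluster
#' @export
simulate_genome <- function(params) {
  stopifnot(inherits(params, "sim_params"))
  p <- params
  needed <- p$cluster_length + p$n_genes * p$gene_length +
    p$n_te_families * p$n_dispersed_insertions_per_family * p$te_length +
    p$n_mirna_loci * p$mirna_length +
    p$n_blacklist_loci * p$blacklist_length
  if (needed * 1.4 + 2000 > p$genome_length)
    stop("sizing error: requested features exceed genome_length (need ~",
         round(needed * 1.4), " bp of ", p$genome_length, ")")

  with_substream(p$seed, "simulate_genome", {
    L <- p$genome_length
    contig <- "chrSim"
    seq_chr <- random_dna(L, p$gc_fraction)
    whole <- IRanges::IRanges(1L, L)
    occupied <- IRanges::IRanges()

    ## --- cluster interval (transcribed from the + strand, like flam) ---
    clus_ir <- .place(p$cluster_length, occupied, whole, gap = 200L)
    occupied <- c(occupied, clus_ir)
    cluster <- GenomicRanges::GRanges(contig, clus_ir, strand = "+")

    ## --- TE family consensus sequences ---
    fams <- if (p$n_te_families > 0L)
      sprintf("TE%02d", seq_len(p$n_te_families)) else character(0)
    cons <- vapply(fams, function(f) random_dna(p$te_length, p$gc_fraction),
                   character(1))
    te_consensus <- Biostrings::DNAStringSet(cons)

    ## --- genes (placed on unique background, outside the cluster) ---
    gene_rows <- list()
    for (i in seq_len(p$n_genes)) {
      ir <- .place(p$gene_length, occupied, whole, gap = 200L)
      occupied <- c(occupied, ir)
      gene_rows[[i]] <- data.frame(
        gene_id = sprintf("gene%03d", i),
        start = IRanges::start(ir), end = IRanges::end(ir),
        strand = sample(c("+", "-"), 1L), stringsAsFactors = FALSE)
    }
    genes_df <- if (length(gene_rows)) do.call(rbind, gene_rows) else
      data.frame(gene_id = character(0), start = integer(0),
                 end = integer(0), strand = character(0))
    genes_df$tss <- ifelse(genes_df$strand == "+", genes_df$start,
                           genes_df$end)

    ## --- dispersed full-length TE insertions ---
    frag_edits <- list()   # sequence edits to apply at the end
    truth_rows <- list()
    ti <- 0L
    for (f in fams) {
      for (j in seq_len(p$n_dispersed_insertions_per_family)) {
        ti <- ti + 1L
        prox_gene <- NA_character_
        ir <- NULL
        strand <- sample(c("+", "-"), 1L)
        if (j == 1L && nrow(genes_df) > 0L) {
          # TE-proximal copy: same strand as a gene, TSS within -10/+15 kb
          for (k in seq_len(200L)) {
            g <- genes_df[sample.int(nrow(genes_df), 1L), ]
            sgn <- if (g$strand == "+") 1L else -1L
            # signed TSS-to-insertion distance on the gene's strand,
            # kept clear of the gene body and inside the -10/+15 kb window
            d <- if (stats::runif(1) < 0.5) round(stats::runif(1, 2100, 14000))
                 else -round(stats::runif(1, 2100, 9000))
            ref <- g$tss - sgn * d   # insertion boundary nearest the TSS
            if (ref < g$tss) { e <- ref; s <- e - p$te_length + 1L }
            else             { s <- ref; e <- s + p$te_length - 1L }
            if (s < 1L || e > L) next
            cand <- IRanges::IRanges(s, e)
            if (any(IRanges::overlapsAny(cand + 50L, occupied))) next
            ir <- cand; strand <- g$strand; prox_gene <- g$gene_id
            break
          }
        }
        if (is.null(ir)) {
          ir <- .place(p$te_length, occupied, whole, gap = 100L)
          prox_gene <- NA_character_
        }
        occupied <- c(occupied, ir)
        ins_seq <- if (strand == "+") cons[[f]] else revcomp_chr(cons[[f]])
        frag_edits[[length(frag_edits) + 1L]] <-
          list(start = IRanges::start(ir), seq = ins_seq)
        truth_rows[[length(truth_rows) + 1L]] <- data.frame(
          copy_id = sprintf("te_copy%04d", ti), family = f, contig = contig,
          start = IRanges::start(ir), end = IRanges::end(ir), strand = strand,
          in_cluster = FALSE, full_length = TRUE, consensus_offset = 1L,
          te_proximal_gene = prox_gene, stringsAsFactors = FALSE)
      }
    }

    ## --- cluster-embedded TE fragments ---
    frag_len <- max(100L, p$te_length %/% 2L)
    occ_clus <- IRanges::IRanges()
    clus_region <- IRanges::IRanges(IRanges::start(clus_ir),
                                    IRanges::end(clus_ir))
    for (f in fams) {
      for (j in seq_len(p$n_cluster_fragments_per_family)) {
        ti <- ti + 1L
        off <- sample.int(p$te_length - frag_len + 1L, 1L)
        frag <- substring(cons[[f]], off, off + frag_len - 1L)
        antisense <- stats::runif(1) < p$antisense_fraction
        # cluster transcribed strand is '+'; antisense fragment = revcomp
        ins_seq <- if (antisense) revcomp_chr(frag) else frag
        strand <- if (antisense) "-" else "+"
        ir <- .place(frag_len, c(occ_clus), clus_region, gap = 100L)
        occ_clus <- c(occ_clus, ir)
        frag_edits[[length(frag_edits) + 1L]] <-
          list(start = IRanges::start(ir), seq = ins_seq)
        truth_rows[[length(truth_rows) + 1L]] <- data.frame(
          copy_id = sprintf("te_copy%04d", ti), family = f, contig = contig,
          start = IRanges::start(ir), end = IRanges::end(ir), strand = strand,
          in_cluster = TRUE, full_length = FALSE, consensus_offset = off,
          te_proximal_gene = NA_character_, stringsAsFactors = FALSE)
      }
    }

    ## --- miRNA and blacklist loci (unique background sequence) ---
    place_simple <- function(n, w, prefix) {
      out <- list()
      for (i in seq_len(n)) {
        ir <- .place(w, occupied, whole, gap = 100L)
        occupied <<- c(occupied, ir)
        out[[i]] <- data.frame(id = sprintf("%s%02d", prefix, i),
                               start = IRanges::start(ir),
                               end = IRanges::end(ir),
                               strand = sample(c("+", "-"), 1L),
                               stringsAsFactors = FALSE)
      }
      if (length(out)) do.call(rbind, out) else
        data.frame(id = character(0), start = integer(0), end = integer(0),
                   strand = character(0))
    }
    mirna_df <- place_simple(p$n_mirna_loci, p$mirna_length, "mir")
    black_df <- place_simple(p$n_blacklist_loci, p$blacklist_length, "rRNA")

    ## --- apply sequence edits ---
    for (e in frag_edits) {
      substring(seq_chr, e$start, e$start + nchar(e$seq) - 1L) <- e$seq
    }

    truth <- if (length(truth_rows)) do.call(rbind, truth_rows) else
      data.frame(copy_id = character(0), family = character(0),
                 contig = character(0), start = integer(0), end = integer(0),
                 strand = character(0), in_cluster = logical(0),
                 full_length = logical(0), consensus_offset = integer(0),
                 te_proximal_gene = character(0))

    contigs <- Biostrings::DNAStringSet(stats::setNames(seq_chr, contig))

    gr <- function(df, extra = NULL) {
      if (nrow(df) == 0L)
        return(GenomicRanges::GRanges(seqnames = character(0),
                                      ranges = IRanges::IRanges()))
      g <- GenomicRanges::GRanges(contig,
                                  IRanges::IRanges(df$start, df$end),
                                  strand = df$strand)
      for (nm in extra) S4Vectors::mcols(g)[[nm]] <- df[[nm]]
      g
    }
    te_insertions <- gr(truth, c("copy_id", "family", "in_cluster",
                                 "full_length", "consensus_offset",
                                 "te_proximal_gene"))
    genes <- gr(genes_df, c("gene_id", "tss"))
    if (nrow(genes_df)) {
      S4Vectors::mcols(genes)$te_proximal_truth <-
        genes_df$gene_id %in% stats::na.omit(truth$te_proximal_gene)
      names(genes) <- genes_df$gene_id
    }
    utr_len <- 300L
    utr3 <- if (nrow(genes_df)) {
      u <- GenomicRanges::GRanges(
        contig,
        IRanges::IRanges(
          ifelse(genes_df$strand == "+", genes_df$end - utr_len + 1L,
                 genes_df$start),
          width = utr_len),
        strand = genes_df$strand)
      S4Vectors::mcols(u)$gene_id <- genes_df$gene_id
      u
    } else GenomicRanges::GRanges()
    mirna_loci <- gr(mirna_df, "id")
    blacklist_loci <- gr(black_df, "id")
    if (nrow(mirna_df)) names(mirna_loci) <- mirna_df$id
    if (nrow(black_df)) names(blacklist_loci) <- black_df$id

    structure(list(contigs = contigs, cluster = cluster,
                   te_consensus = te_consensus,
                   te_insertions = te_insertions, genes = genes, utr3 = utr3,
                   mirna_loci = mirna_loci,
                   blacklist_loci = blacklist_loci,
                   truth = truth, params = p),
              class = "GenomeBundle")
  })
}

#' @export
print.GenomeBundle <- function(x, ...) {
  cat("GenomeBundle:", sum(Biostrings::width(x$contigs)), "bp in",
      length(x$contigs), "contig(s)\n")
  cat("  cluster:", as.character(GenomicRanges::seqnames(x$cluster)), ":",
      GenomicRanges::start(x$cluster), "-", GenomicRanges::end(x$cluster),
      "(", as.character(GenomicRanges::strand(x$cluster)), ")\n")
  cat("  TE families:", length(x$te_consensus),
      "| insertions:", length(x$te_insertions),
      "| genes:", length(x$genes),
      "| miRNA loci:", length(x$mirna_loci),
      "| blacklist:", length(x$blacklist_loci), "\n")
  invisible(x)
}

# Extract the genomic sequence of intervals, strand-aware (a '-' feature
# returns the reverse complement, i.e. the feature's own 5'->3' sequence).
feature_seq <- function(bundle, gr) {
  seqs <- Biostrings::DNAStringSet(vapply(seq_along(gr), function(i) {
    s <- substring(as.character(
      bundle$contigs[[as.character(GenomicRanges::seqnames(gr[i]))]]),
      GenomicRanges::start(gr[i]), GenomicRanges::end(gr[i]))
    if (as.character(GenomicRanges::strand(gr[i])) == "-")
      revcomp_chr(s) else s
  }, character(1)))
  seqs
}
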