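#' Count reads per feature
#'
#' Transposon-level counting (`level = "te"`) includes randomly assigned
#' multimappers and aggregates all insertions of a family; gene-level
#' counting (`level = "gene"`) uses uniquely mapping reads only. A read
#' counts for at most one feature: overlapping same-level annotations are
#' resolved by longest overlap, ties by lexicographically first feature id.
#'
#' @param assigned data.frame of assigned alignments (read_id, contig,
#'   start, end, strand, n_hits).
#' @param features Stranded `GRanges`: for `"te"` the insertion intervals
#'   with a `family` column; for `"gene"` the genes with a `gene_id` column.
#' @param level `"te"` or `"gene"`.
#' @return Named integer vector of counts (per family or per gene).
#' @export
count_features <- function(assigned, features, level = c("te", "gene")) {
  level <- match.arg(level)
  df <- assigned
  if (level == "gene") df <- df[df$n_hits == 1L, , drop = FALSE]
  ids <- if (level == "te") S4Vectors::mcols(features)$family else
    S4Vectors::mcols(features)$gene_id
  if (is.null(ids)) stop("features lack the required id column")
  out_names <- sort(unique(ids))
  counts <- stats::setNames(integer(length(out_names)), out_names)
  if (nrow(df) == 0L || length(features) == 0L) return(counts)
  reads_gr <- GenomicRanges::GRanges(df$contig,
                                     IRanges::IRanges(df$start, df$end))
  ov <- GenomicRanges::findOverlaps(reads_gr, features,
                                    ignore.strand = TRUE)
  if (length(ov) == 0L) return(counts)
  qh <- S4Vectors::queryHits(ov); sh <- S4Vectors::subjectHits(ov)
  ow <- GenomicRanges::width(IRanges::pintersect(reads_gr[qh],
                                                 features[sh]))
  # longest overlap wins; ties to the lexicographically first feature id
  o <- order(qh, -ow, ids[sh])
  qh <- qh[o]; sh <- sh[o]
  keep <- !duplicated(qh)
  tab <- table(ids[sh[keep]])
  counts[names(tab)] <- counts[names(tab)] + as.integer(tab)
  counts
}

#' Assemble a feature count matrix
#'
#' @param sample_counts Named list of equally named count vectors (from
#'   [count_features()]), one per sample.
#' @param totals Named numeric of library totals (same names).
#' @return A `FeatureCountMatrix`: list with `counts` (features x samples),
#'   `totals`, and `rpm`.
#' @export
feature_count_matrix <- function(sample_counts, totals) {
  stopifnot(identical(names(sample_counts), names(totals)))
  counts <- do.call(cbind, sample_counts)
  rpm <- sweep(counts, 2L, as.numeric(totals), function(x, t) 1e6 * x / t)
  structure(list(counts = counts, totals = totals, rpm = rpm),
            class = "FeatureCountMatrix")
}

#' Per-feature fold-change table (MA coordinates)
#'
#' log2 fold-changes on pseudo-counted rpm: the pseudo-count (in raw count
#' units) is added before rpm scaling, so features absent from one library
#' stay finite. The MA x-coordinate is the mean rpm across the contrast.
#'
#' @param mat A [feature_count_matrix()].
#' @param case,control Sample names.
#' @param pseudo Pseudo-count in raw count units (default 1; 0 reproduces
#'   plain ratios).
#' @return data.frame: feature, case_rpm, control_rpm, mean_rpm, log2fc.
#' @export
fold_change_table <- function(mat, case, control, pseudo = 1) {
  stopifnot(inherits(mat, "FeatureCountMatrix"),
            all(c(case, control) %in% colnames(mat$counts)))
  case_rpm <- 1e6 * (mat$counts[, case] + pseudo) /
    as.numeric(mat$totals[[case]])
  ctrl_rpm <- 1e6 * (mat$counts[, control] + pseudo) /
    as.numeric(mat$totals[[control]])
  data.frame(feature = rownames(mat$counts),
             case_rpm = 1e6 * mat$counts[, case] /
               as.numeric(mat$totals[[case]]),
             control_rpm = 1e6 * mat$counts[, control] /
               as.numeric(mat$totals[[control]]),
             mean_rpm = (case_rpm + ctrl_rpm) / 2,
             log2fc = log2(case_rpm / ctrl_rpm),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Call de-regulated features
#'
#' A feature is `up` when its linear fold-change exceeds `fc_thresh` with
#' adjusted p-value below `alpha` (both strict), `down` symmetrically when
#' the fold-change is below `1 / fc_thresh`; anything else (including
#' missing adjusted p-values) is `unchanged`. Adjusted p-values are an
#' externally supplied column: this package computes no differential
#' statistics.
#'
#' @param fc_table data.frame with `feature` and `log2fc` columns (e.g.
#'   from [fold_change_table()]).
#' @param padj Numeric vector of adjusted p-values aligned with `fc_table`
#'   rows (NA allowed).
#' @param fc_thresh Linear fold-change threshold (default 4).
#' @param alpha Adjusted p-value threshold (default 0.05).
#' @return `fc_table` with columns `padj` and `flag`
#'   (`up`/`down`/`unchanged`).
#' @export
classify_deregulated <- function(fc_table, padj, fc_thresh = 4,
                                 alpha = 0.05) {
  stopifnot(length(padj) == nrow(fc_table))
  if (any(!is.na(padj) & (padj < 0 | padj > 1)))
    stop("padj must be in [0,1] or NA")
  fc <- 2^fc_table$log2fc
  sig <- !is.na(padj) & padj < alpha
  flag <- rep("unchanged", nrow(fc_table))
  flag[sig & fc > fc_thresh] <- "up"
  flag[sig & fc < 1 / fc_thresh] <- "down"
  out <- fc_table
  out$padj <- padj
  out$flag <- flag
  out
}

#' Flag genes with a nearby same-strand TE insertion
#'
#' A gene promoter is TE-proximal when some insertion on the gene's strand
#' has its TSS-nearest boundary at a signed distance `d` (measured on the
#' gene's strand: negative = promoter downstream of the insertion) within
#' `[-up, +down]`; a TSS inside an insertion is distance 0. With
#' `orientation = "genomic"` the window is applied in genomic left/right
#' coordinates instead (same-strand requirement unchanged).
#'
#' @param genes Stranded `GRanges` with a `tss` metadata column (genomic
#'   TSS coordinate) and `gene_id`.
#' @param te_insertions Stranded `GRanges` of insertion intervals.
#' @param up,down Window bounds in bp (defaults -10 kb / +15 kb).
#' @param orientation `"gene_strand"` (default) or `"genomic"`.
#' @return Logical vector, one flag per gene.
#' @export
flag_te_proximal <- function(genes, te_insertions, up = 10000L,
                             down = 15000L,
                             orientation = c("gene_strand", "genomic")) {
  orientation <- match.arg(orientation)
  tss <- S4Vectors::mcols(genes)$tss
  if (is.null(tss))
    tss <- ifelse(as.character(GenomicRanges::strand(genes)) == "+",
                  GenomicRanges::start(genes), GenomicRanges::end(genes))
  gstr <- as.character(GenomicRanges::strand(genes))
  gct <- as.character(GenomicRanges::seqnames(genes))
  istr <- as.character(GenomicRanges::strand(te_insertions))
  ict <- as.character(GenomicRanges::seqnames(te_insertions))
  is_ <- GenomicRanges::start(te_insertions)
  ie_ <- GenomicRanges::end(te_insertions)
  vapply(seq_along(genes), function(i) {
    sel <- istr == gstr[i] & ict == gct[i]
    if (!any(sel)) return(FALSE)
    ref <- ifelse(tss[i] < is_[sel], is_[sel],
                  ifelse(tss[i] > ie_[sel], ie_[sel], tss[i]))
    sgn <- if (orientation == "genomic" || gstr[i] == "+") 1L else -1L
    d <- sgn * (tss[i] - ref)
    any(d >= -up & d <= down)
  }, logical(1))
}

#' Relative qPCR quantification (delta-delta-Ct)
#'
#' For each target and condition, replicate delta-Ct values
#' (`Ct_target - Ct_reference`, paired by replicate) are averaged; the
#' delta-delta-Ct is the difference of mean delta-Ct between a condition
#' and the control condition, and the fold-change is `2^-ddCt`. The
#' replicate SD of delta-Ct is propagated as a fold-change range
#' `2^-(ddCt +/- sd)`.
#'
#' @param ct data.frame with columns `gene`, `condition`, `replicate`,
#'   `ct` (Ct values, > 0).
#' @param reference Reference gene id (e.g. `"rp49"`); must be measured in
#'   every condition/replicate.
#' @param control Control condition id.
#' @return data.frame: target, condition, n_replicates, mean_dct, sd_dct,
#'   ddct, fold, fold_lower, fold_upper.
#' @examples
#' ct <- expand.grid(gene = c("mdg1", "rp49"), condition = c("ctrl", "kd"),
#'                   replicate = 1:3, stringsAsFactors = FALSE)
#' ct$ct <- c(25, 18, 24, 18, 25, 18, 24, 18, 25, 18, 24, 18)
#' ddct(ct, reference = "rp49", control = "ctrl")
#' @export
ddct <- function(ct, reference, control) {
  stopifnot(all(c("gene", "condition", "replicate", "ct") %in% names(ct)))
  if (any(ct$ct <= 0)) stop("Ct values must be positive")
  if (!reference %in% ct$gene) stop("missing reference Ct: ", reference)
  if (!control %in% ct$condition) stop("control condition not found")
  ref <- ct[ct$gene == reference, c("condition", "replicate", "ct")]
  names(ref)[3] <- "ct_ref"
  tgt <- ct[ct$gene != reference, , drop = FALSE]
  m <- merge(tgt, ref, by = c("condition", "replicate"))
  if (nrow(m) < nrow(tgt))
    stop("missing reference Ct for some condition/replicate pairs")
  m$dct <- m$ct - m$ct_ref
  agg <- stats::aggregate(dct ~ gene + condition, data = m,
                          FUN = function(x) c(mean = mean(x),
                                              sd = stats::sd(x),
                                              n = length(x)))
  agg <- data.frame(target = agg$gene, condition = agg$condition,
                    mean_dct = agg$dct[, "mean"], sd_dct = agg$dct[, "sd"],
                    n_replicates = agg$dct[, "n"], stringsAsFactors = FALSE)
  ctrl <- agg[agg$condition == control, c("target", "mean_dct")]
  names(ctrl)[2] <- "ctrl_dct"
  out <- merge(agg, ctrl, by = "target")
  out$ddct <- out$mean_dct - out$ctrl_dct
  out$fold <- 2^(-out$ddct)
  out$fold_lower <- 2^(-(out$ddct + out$sd_dct))
  out$fold_upper <- 2^(-(out$ddct - out$sd_dct))
  out[order(out$target, out$condition),
      c("target", "condition", "n_replicates", "mean_dct", "sd_dct",
        "ddct", "fold", "fold_lower", "fold_upper")]
}
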