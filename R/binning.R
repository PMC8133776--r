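#' Tile an interval into bins or sliding windows
#'
#' Non-overlapping mode tiles `floor(L / width)` full bins from the
#' interval's 5' end (the trailing partial bin is dropped when
#' `full_bins_only`); sliding mode returns every window of `width` starting
#' at `start + j * step` that lies fully inside the interval, i.e.
#' `floor((L - width) / step) + 1` windows for `L >= width`.
#'
#' Bins carry a `bin_index` column in transcriptional 5'-to-3' order: for a
#' `-` strand interval the index runs against genomic coordinates so that
#' "3'" is always the transcriptional 3' end.
#'
#' @param interval A length-1 stranded `GRanges`.
#' @param width Bin width in bp.
#' @param step Step in bp (sliding mode; defaults to `width`).
#' @param mode `"nonoverlapping"` or `"sliding"`.
#' @param full_bins_only Drop a trailing partial bin (non-overlapping mode)?
#' @return A `GRanges` of bins (sorted by genomic coordinate) with metadata
#'   column `bin_index`.
#' @examples
#' gr <- GenomicRanges::GRanges("chrX", IRanges::IRanges(1, 650972), "+")
#' length(tile_interval(gr, 1000))                          # 650
#' length(tile_interval(gr, 100000, 1000, mode = "sliding")) # 551
#' @export
tile_interval <- function(interval, width, step = width,
                          mode = c("nonoverlapping", "sliding"),
                          full_bins_only = TRUE) {
  mode <- match.arg(mode)
  stopifnot(is(interval, "GRanges"), length(interval) == 1L, width > 0L)
  width <- as.integer(width); step <- as.integer(step)
  if (mode == "nonoverlapping" && step != width)
    stop("step must equal width in nonoverlapping mode")
  L <- GenomicRanges::width(interval)
  s0 <- GenomicRanges::start(interval)
  if (mode == "nonoverlapping") {
    nb <- L %/% width
    starts <- s0 + (seq_len(nb) - 1L) * width
    widths <- rep(width, nb)
    if (!full_bins_only && L %% width > 0L) {
      starts <- c(starts, s0 + nb * width)
      widths <- c(widths, L %% width)
    }
  } else {
    if (L < width) {
      warning("interval shorter than window width; no windows")
      starts <- integer(0); widths <- integer(0)
    } else {
      nw <- (L - width) %/% step + 1L
      starts <- s0 + (seq_len(nw) - 1L) * step
      widths <- rep(width, nw)
    }
  }
  if (length(starts) == 0L) {
    bins <- GenomicRanges::GRanges()
    S4Vectors::mcols(bins)$bin_index <- integer(0)
    return(bins)
  }
  bins <- GenomicRanges::GRanges(
    GenomicRanges::seqnames(interval),
    IRanges::IRanges(starts, width = widths),
    strand = GenomicRanges::strand(interval))
  idx <- seq_along(bins)
  if (as.character(GenomicRanges::strand(interval)) == "-") idx <- rev(idx)
  S4Vectors::mcols(bins)$bin_index <- idx
  bins
}

#' Count assigned reads per bin
#'
#' @param assigned data.frame of assigned alignments (read_id, contig,
#'   start, end, strand, n_hits), e.g. from [assign_multimappers()].
#' @param bins `GRanges` from [tile_interval()].
#' @param unique_only Keep only reads with `n_hits == 1`?
#' @param strand `"sense"` keeps reads matching the bins' (cluster's)
#'   transcribed strand; `"both"` is unstranded.
#' @param overlap_rule `"contained"` counts a read for a bin only when its
#'   span lies fully within the bin (reads straddling a bin boundary are
#'   ambiguous and uncounted, matching union-mode counting on disjoint
#'   features); `"half_overlap"` counts a read for every window containing
#'   at least 50 percent of its span.
#' @return Integer vector of counts, one per bin (in the order of `bins`),
#'   with attributes `n_eligible`, `n_ambiguous` (eligible reads touching a
#'   bin but contained in none; contained rule only) and `n_outside`.
#' @export
count_bins <- function(assigned, bins, unique_only = TRUE,
                       strand = c("sense", "both"),
                       overlap_rule = c("contained", "half_overlap")) {
  strand <- match.arg(strand)
  overlap_rule <- match.arg(overlap_rule)
  df <- assigned
  if (unique_only) df <- df[df$n_hits == 1L, , drop = FALSE]
  if (strand == "sense") {
    bstrand <- as.character(GenomicRanges::strand(bins))[1]
    df <- df[df$strand == bstrand, , drop = FALSE]
  }
  counts <- integer(length(bins))
  n_eligible <- nrow(df)
  if (n_eligible == 0L) {
    attr(counts, "n_eligible") <- 0L
    attr(counts, "n_ambiguous") <- 0L
    attr(counts, "n_outside") <- 0L
    return(counts)
  }
  reads_gr <- GenomicRanges::GRanges(df$contig,
                                     IRanges::IRanges(df$start, df$end))
  if (overlap_rule == "contained") {
    ov <- GenomicRanges::findOverlaps(reads_gr, bins, type = "within",
                                      ignore.strand = TRUE)
    qh <- S4Vectors::queryHits(ov)
    # a read fully inside two overlapping bins would be double-counted;
    # with non-overlapping bins each read lands in at most one
    tab <- tabulate(S4Vectors::subjectHits(ov), nbins = length(bins))
    touching <- IRanges::overlapsAny(reads_gr, bins, ignore.strand = TRUE)
    n_ambiguous <- sum(touching) - length(unique(qh))
    n_outside <- sum(!touching)
  } else {
    ov <- GenomicRanges::findOverlaps(reads_gr, bins, ignore.strand = TRUE)
    qh <- S4Vectors::queryHits(ov); sh <- S4Vectors::subjectHits(ov)
    ow <- GenomicRanges::width(IRanges::pintersect(reads_gr[qh], bins[sh]))
    keep <- ow * 2L >= GenomicRanges::width(reads_gr)[qh]
    tab <- tabulate(sh[keep], nbins = length(bins))
    n_ambiguous <- 0L
    n_outside <- sum(!IRanges::overlapsAny(reads_gr, bins,
                                           ignore.strand = TRUE))
  }
  counts <- as.integer(tab)
  attr(counts, "n_eligible") <- n_eligible
  attr(counts, "n_ambiguous") <- as.integer(n_ambiguous)
  attr(counts, "n_outside") <- as.integer(n_outside)
  counts
}

#' Reads-per-million normalisation
#'
#' @param counts Numeric vector of raw counts.
#' @param library_total_mapped Library size: all genome-mapped reads for
#'   1 kb bin analyses, uniquely aligned reads for the 100 kb sliding-window
#'   analysis.
#' @return `1e6 * counts / library_total_mapped`.
#' @export
rpm_normalize <- function(counts, library_total_mapped) {
  if (length(library_total_mapped) != 1L || library_total_mapped <= 0)
    stop("library_total_mapped must be a single positive number")
  1e6 * as.numeric(counts) / as.numeric(library_total_mapped)
}

#' Fold-change rule variants
#'
#' Three preset rule sets for per-bin log2 fold-changes:
#' \describe{
#'   \item{osc_1kb}{somatic cell line, 1 kb bins: bins with 0 rpm in more
#'     than one sample are discarded; pseudo-count 0.01 (the discard rule
#'     still admits a single zero, so a small pseudo-count keeps the
#'     fold-change finite).}
#'   \item{ovary_1kb}{ovary, 1 kb bins: pseudo-count 0.01; bins with 0 rpm
#'     only in the control are discarded.}
#'   \item{sliding_100kb}{100 kb sliding windows: pseudo-count 1, no
#'     discard rule.}
#' }
#'
#' @param name One of the preset names, or `"custom"`.
#' @param pseudo_count,discard Override the preset (for `"custom"`,
#'   required): `discard` is one of `"zero_in_gt1_sample"`,
#'   `"zero_only_in_control"`, `"none"`.
#' @return An `fc_variant` list with `name`, `pseudo_count`, `discard`.
#' @export
fc_variant <- function(name = c("osc_1kb", "ovary_1kb", "sliding_100kb",
                                "custom"),
                       pseudo_count = NULL, discard = NULL) {
  name <- match.arg(name)
  preset <- switch(name,
    osc_1kb = list(pseudo_count = 0.01, discard = "zero_in_gt1_sample"),
    ovary_1kb = list(pseudo_count = 0.01, discard = "zero_only_in_control"),
    sliding_100kb = list(pseudo_count = 1, discard = "none"),
    custom = list(pseudo_count = pseudo_count, discard = discard))
  if (!is.null(pseudo_count)) preset$pseudo_count <- pseudo_count
  if (!is.null(discard)) preset$discard <- discard
  if (is.null(preset$pseudo_count) || is.null(preset$discard))
    stop("custom variant needs pseudo_count and discard")
  preset$discard <- match.arg(preset$discard,
                              c("zero_in_gt1_sample",
                                "zero_only_in_control", "none"))
  structure(c(list(name = name), preset), class = "fc_variant")
}

#' Per-bin log2 fold-changes under a rule variant
#'
#' Computes `log2((case + pc) / (control + pc))` per bin after applying the
#' variant's discard rule across all samples of the experiment. Discarded
#' bins are kept in the table with `keep = FALSE` and a reason.
#'
#' @param rpm Numeric matrix of per-bin rpm, bins x samples, with column
#'   names; rows in 5'-to-3' bin order (or pass `bin_index`).
#' @param case,control Column names of the contrast.
#' @param variant An [fc_variant()].
#' @param bin_index Optional explicit 5'-to-3' indices (default rows).
#' @return data.frame: bin_index, case_rpm, control_rpm, log2fc, keep,
#'   reason.
#' @export
bin_log2fc <- function(rpm, case, control, variant = fc_variant("osc_1kb"),
                       bin_index = seq_len(nrow(rpm))) {
  stopifnot(inherits(variant, "fc_variant"), is.matrix(rpm),
            all(c(case, control) %in% colnames(rpm)))
  pc <- variant$pseudo_count
  keep <- rep(TRUE, nrow(rpm))
  reason <- rep(NA_character_, nrow(rpm))
  if (variant$discard == "zero_in_gt1_sample") {
    bad <- rowSums(rpm == 0) > 1L
    keep[bad] <- FALSE; reason[bad] <- "zero_in_gt1_sample"
  } else if (variant$discard == "zero_only_in_control") {
    bad <- rpm[, control] == 0 & rpm[, case] > 0
    keep[bad] <- FALSE; reason[bad] <- "zero_only_in_control"
  }
  data.frame(bin_index = bin_index,
             case_rpm = rpm[, case], control_rpm = rpm[, control],
             log2fc = log2((rpm[, case] + pc) / (rpm[, control] + pc)),
             keep = keep, reason = reason, stringsAsFactors = FALSE)
}

#' Positional 5'-to-3' gradient of per-bin fold-changes
#'
#' Summarises whether fold-changes become more extreme towards the
#' transcriptional 3' end: Spearman rank correlation of log2FC against the
#' 5'-to-3' bin index (rho < 0 means a loss that is more pronounced towards
#' the 3' end), plus the least-squares slope in log2FC per bin.
#'
#' @param fc_table data.frame from [bin_log2fc()] (only `keep` rows are
#'   used), or any data.frame with `bin_index` and `log2fc`.
#' @return List: `rho`, `p_value`, `slope`, `n_bins`. All NA (with a
#'   warning) when fewer than 10 bins are kept.
#' @export
positional_gradient <- function(fc_table) {
  df <- fc_table
  if ("keep" %in% names(df)) df <- df[df$keep, , drop = FALSE]
  if (nrow(df) < 10L) {
    warning("fewer than 10 kept bins; gradient not computed")
    return(list(rho = NA_real_, p_value = NA_real_, slope = NA_real_,
                n_bins = nrow(df)))
  }
  if (stats::sd(df$log2fc) == 0) {
    # constant fold-change: no gradient by definition
    return(list(rho = 0, p_value = 1, slope = 0, n_bins = nrow(df)))
  }
  ct <- suppressWarnings(stats::cor.test(df$bin_index, df$log2fc,
                                         method = "spearman"))
  fit <- stats::lm(log2fc ~ bin_index, data = df)
  list(rho = unname(ct$estimate), p_value = ct$p.value,
       slope = unname(stats::coef(fit)[2]), n_bins = nrow(df))
}

#' Pool replicate libraries
#'
#' Element-wise sum of per-bin (or per-feature) counts across replicates,
#' with library totals summed correspondingly, so pooled rpm equals the
#' count-weighted combination of replicate rpms.
#'
#' @param counts_list List of equal-length numeric count vectors (shared
#'   bin/feature set; names, if present, must agree).
#' @param totals Numeric vector of library totals, one per replicate.
#' @return List with `counts` (summed vector) and `total` (summed totals).
#' @export
pool_replicates <- function(counts_list, totals) {
  stopifnot(length(counts_list) >= 1L,
            length(totals) == length(counts_list))
  len <- lengths(counts_list)
  if (length(unique(len)) != 1L)
    stop("replicates have mismatched bin sets")
  nms <- lapply(counts_list, names)
  if (!all(vapply(nms, function(x) identical(x, nms[[1]]), logical(1))))
    stop("replicates have mismatched bin sets")
  list(counts = Reduce(`+`, counts_list), total = sum(totals))
}
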