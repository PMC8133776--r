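#' Study-condition expression profiles
#'
#' The three canonical conditions exercised against a simulated genome:
#' `control` (uniform cluster expression), `nup_like` (5'-to-3' positional
#' decay, `decay = 1.5`, emulating destabilisation of distal transcript
#' regions), and `zuc_like` (uniform two-fold up-regulation, `scale = 2`,
#' emulating a processing block). All three share gene expression rates
#' that make the cluster a minor library component (about 2 percent of
#' mapped reads in the control), as a piRNA cluster is against a
#' transcriptome, so that rpm normalisation can register cluster-level
#' changes.
#'
#' @param bundle A `GenomeBundle`.
#' @param base_rate Cluster read-start weight per bp (control).
#' @param gene_rate Expected relative read weight per gene.
#' @return Named list of three [expression_profile()] objects.
#' @export
study_profiles <- function(bundle, base_rate = 0.02, gene_rate = 3000) {
  rates <- stats::setNames(rep(gene_rate, length(bundle$genes)),
                           bundle$genes$gene_id)
  list(control = expression_profile(base_rate, 1, 0, rates),
       nup_like = expression_profile(base_rate, 1, 1.5, rates),
       zuc_like = expression_profile(base_rate, 2, 0, rates))
}

#' Run the binned cluster fold-change analysis end to end
#'
#' Simulates a case and a control RNA-seq library, aligns both with the
#' exact-match aligner, assigns multimappers, counts uniquely mapped
#' sense-strand reads in mappability-filtered cluster bins, normalises to
#' rpm over all genome-mapped reads, computes per-bin log2 fold-changes
#' under a rule variant, and summarises the 5'-to-3' positional gradient.
#'
#' @param bundle A `GenomeBundle`.
#' @param case_profile,control_profile [expression_profile()] objects.
#' @param depth Reads per library.
#' @param seed Integer seed (substreams derive the per-library seeds).
#' @param read_length Read length in bp.
#' @param bin_width Bin width in bp.
#' @param k Mappability k-mer length (default 45: 50 bp reads minus the 5
#'   trimmed leading bases).
#' @param map_threshold Strict mappability cutoff for bins.
#' @param variant An [fc_variant()].
#' @return List: `fc` (per-bin table), `gradient`, `bins` (kept bins),
#'   `totals` (mapped reads per library), `n_bins_total`.
#' @export
run_cluster_contrast <- function(bundle, case_profile, control_profile,
                                 depth = 2e5, seed = 1L, read_length = 50L,
                                 bin_width = 1000L, k = 45L,
                                 map_threshold = 0.8,
                                 variant = fc_variant("osc_1kb")) {
  track <- kmer_uniqueness_track(bundle, k = k)
  all_bins <- tile_interval(bundle$cluster, bin_width)
  bins <- filter_by_mappability(all_bins, track, map_threshold)
  one <- function(profile, tag) {
    rs <- simulate_cluster_rnaseq(bundle, profile, read_length, depth,
                                  seed = substream_seed(seed, tag))
    asg <- assign_multimappers(exact_align(rs, bundle),
                               seed = substream_seed(seed, paste0(tag,
                                                                  "_mm")))
    list(counts = count_bins(asg, bins), total = nrow(asg))
  }
  ctrl <- one(control_profile, "control")
  case <- one(case_profile, "case")
  rpm <- cbind(control = rpm_normalize(ctrl$counts, ctrl$total),
               case = rpm_normalize(case$counts, case$total))
  fc <- bin_log2fc(rpm, "case", "control", variant,
                   bin_index = bins$bin_index)
  list(fc = fc, gradient = positional_gradient(fc), bins = bins,
       totals = c(control = ctrl$total, case = case$total),
       n_bins_total = length(all_bins))
}
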