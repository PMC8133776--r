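# pirnaquant

Mappability-aware quantification of piRNA cluster expression, small RNA
library processing, and RNA-FISH focus counting — with a seeded
synthetic-data generator so every analysis is testable against ground
truth.

## The problem

Uni-strand piRNA clusters such as *Drosophila flamenco* (~650 kb of
transposon remnants on chromosome X) produce the piRNAs that silence
somatic retrotransposons. Asking *where* along such a locus transcript
levels change — for example, whether a knockdown destabilises the
transcript preferentially towards its 3′ end — requires restricting the
analysis to positions where short reads map uniquely, binning the locus,
and comparing mappability-filtered per-bin fold-changes between
conditions.

For a cluster of length *L* tiled into bins *b = 1 … B* (5′→3′), the core
statistic is the per-bin fold-change

    log2FC_b = log2( (rpm_b^case + pc) / (rpm_b^control + pc) )

computed over bins whose k-mer mappability (fraction of k-mer starts in
the bin whose canonical k-mer occurs at exactly one genomic locus) exceeds
a strict threshold, with the pseudo-count *pc* and zero-bin discard rules
depending on the analysis variant (1 kb bins: *pc* = 0.01; 100 kb sliding
windows: *pc* = 1). The positional trend is summarised by the Spearman
rank correlation ρ of log2FC against the 5′→3′ bin index: ρ < 0 with
small p indicates a loss more pronounced towards the 3′ end.

Around this core, the package provides the supporting analyses: a small
RNA processing chain (adapter clipping, trimming of the 4 nt randomized
adapter ends, rRNA/tRNA removal, seeded random placement of multimappers,
length/feature/orientation classification, miRNA-anchored normalisation),
gene/TE-family count matrices with fourfold de-regulation calls and a
−10 kb/+15 kb same-strand TE-proximity promoter rule, ΔΔCt qPCR
quantification, and difference-of-Gaussians quantification of nuclear
versus cytoplasmic RNA-FISH foci and perinuclear body particles.

## Worked example

```r
library(pirnaquant)

# a 500 kb toy genome: 60 kb uni-strand cluster of TE fragments whose
# families also have dispersed full-length copies (real multimapping)
bundle <- simulate_genome(sim_params(seed = 1))
bundle
#> GenomeBundle: 500000 bp in 1 contig(s)
#>   cluster: chrSim : 22956 - 82955 ( + )
#>   TE families: 4 | insertions: 24 | genes: 20 | miRNA loci: 5 | blacklist: 2

# control vs a condition with 5'-to-3' positional decay (decay = 1.5)
profs <- study_profiles(bundle)
res <- run_cluster_contrast(bundle, profs$nup_like, profs$control,
                            depth = 5e4, seed = 2)
sum(res$fc$keep)    # 46 of 60 one-kb bins survive mappability > 0.8
res$gradient
#> $rho      -0.692        # negative: loss grows towards the 3' end
#> $p_value  9.83e-08
#> $slope    -0.0343       # log2FC per bin
#> $n_bins   46

# nuclear vs cytoplasmic RNA-FISH foci on a synthetic image
im <- synthesize_cell_image(n_spots_in = 4, n_spots_out = 6, seed = 3)
quantify_foci(im)
#> FociResult: N_nuc = 4 | n_dots = 10 ( 4 nuclear )
```

The gradient output reads: across the 46 mappable bins, per-bin
fold-changes decline monotonically enough along the cluster to give a
rank correlation of −0.69 (p ≈ 1e-7) — the binned signature of a
transcript destabilised with a 3′ bias — while the focus counter recovers
exactly the 4 nuclear and 6 cytoplasmic spots that were rendered.

See the vignette (`vignettes/cluster-quantification.Rmd`) for the model,
parameter meanings, rule variants, and the design decisions behind each
default.

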