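mk_asg <- function(start, end, n_hits = 1L, strand = "+",
                   contig = "chrSim") {
  data.frame(read_id = sprintf("r%03d", seq_along(start)), contig = contig,
             start = start, end = end, strand = strand,
             width = end - start + 1L, n_hits = n_hits,
             stringsAsFactors = FALSE)
}

test_that("feature counting respects level policies and tie-breaks", {
  b <- small_bundle()
  g <- b$genes[1]
  gs <- GenomicRanges::start(g)
  asg <- mk_asg(start = gs + seq(0, 450, by = 50), end = gs +
                  seq(0, 450, by = 50) + 49L)
  cnt <- count_features(asg, b$genes, level = "gene")
  expect_identical(unname(cnt[g$gene_id]), 10L)
  expect_identical(sum(cnt), 10L)
  # a multimapper assigned to a TE insertion counts at TE level only
  te <- b$te_insertions[!b$te_insertions$in_cluster][2]
  ts <- GenomicRanges::start(te)
  mm <- mk_asg(ts + 10L, ts + 59L, n_hits = 3L)
  expect_identical(unname(count_features(mm, b$te_insertions,
                                         level = "te")[te$family]), 1L)
  expect_identical(sum(count_features(mm, b$genes, level = "gene")), 0L)
  # longest overlap wins; ties go to the lexicographically first id
  feats <- GenomicRanges::GRanges("chrSim",
                                  IRanges::IRanges(c(100, 160), c(200, 260)),
                                  strand = "+")
  S4Vectors::mcols(feats)$gene_id <- c("gB", "gA")
  r_long <- mk_asg(150L, 199L)           # 50 nt in gB, 40 in gA
  expect_identical(unname(count_features(r_long, feats, "gene")["gB"]), 1L)
  tie_feats <- GenomicRanges::GRanges("chrSim",
                                      IRanges::IRanges(c(100, 100),
                                                       c(300, 300)))
  S4Vectors::mcols(tie_feats)$gene_id <- c("gB", "gA")
  r_tie <- mk_asg(120L, 169L)
  expect_identical(unname(count_features(r_tie, tie_feats, "gene")["gA"]),
                   1L)
})

test_that("per-family counts match the generator ledger for in-family reads", {
  b <- small_bundle()
  # one read drawn verbatim from inside each full-length insertion
  full <- b$te_insertions[b$te_insertions$full_length]
  starts <- GenomicRanges::start(full) + 25L
  asg <- mk_asg(starts, starts + 49L,
                strand = as.character(GenomicRanges::strand(full)))
  cnt <- count_features(asg, b$te_insertions, level = "te")
  expected <- table(full$family)
  expect_identical(unname(cnt[names(expected)]),
                   as.integer(expected))
})

test_that("fold-change tables reproduce closed-form values", {
  mat <- feature_count_matrix(
    list(ctrl = c(a = 20L, b = 100L), case = c(a = 80L, b = 100L)),
    totals = c(ctrl = 1e6, case = 1e6))
  fc0 <- fold_change_table(mat, "case", "ctrl", pseudo = 0)
  expect_equal(fc0$log2fc[fc0$feature == "a"], 2)
  expect_equal(fc0$mean_rpm[fc0$feature == "a"], 50)
  # identical samples: all zero
  same <- feature_count_matrix(list(x = c(a = 5L), y = c(a = 5L)),
                               totals = c(x = 100, y = 100))
  expect_equal(fold_change_table(same, "x", "y")$log2fc, 0)
  # monotone in the case count for fixed control
  ms <- feature_count_matrix(
    list(ctrl = c(a = 10L, b = 10L, c = 10L),
         case = c(a = 5L, b = 10L, c = 40L)),
    totals = c(ctrl = 1000, case = 1000))
  fcs <- fold_change_table(ms, "case", "ctrl")
  expect_true(all(diff(fcs$log2fc[order(ms$counts[, "case"])]) > 0))
})

test_that("de-regulation calls use strict fourfold and alpha cuts", {
  fc <- data.frame(feature = c("a", "b", "c", "d", "e"),
                   log2fc = log2(c(4.1, 4.1, 3.9, 1 / 4.1, 10)))
  calls <- classify_deregulated(fc, padj = c(0.04, 0.05, 0.001, 0.01, NA))
  expect_identical(calls$flag, c("up", "unchanged", "unchanged", "down",
                                 "unchanged"))
  expect_error(classify_deregulated(fc, padj = c(0.1, 2, 0, 0, 0)), "padj")
  # swapping case and control exchanges up and down labels
  swapped <- classify_deregulated(
    data.frame(feature = fc$feature, log2fc = -fc$log2fc),
    padj = c(0.04, 0.05, 0.001, 0.01, NA))
  expect_identical(swapped$flag,
                   c("down", "unchanged", "unchanged", "up", "unchanged"))
})

test_that("TE-proximity uses the signed -10/+15 kb window on the gene strand", {
  mk_gene <- function(tss, strand) {
    g <- GenomicRanges::GRanges("c", IRanges::IRanges(tss, tss + 10L),
                                strand = strand)
    S4Vectors::mcols(g)$tss <- tss
    g
  }
  ins <- function(pos, strand)
    GenomicRanges::GRanges("c", IRanges::IRanges(pos, pos),
                           strand = strand)
  # '+' gene TSS 5000, '+' insertion at 10000: d = -5000, flagged
  expect_true(flag_te_proximal(mk_gene(5000L, "+"), ins(10000L, "+")))
  # '+' gene TSS 30000, insertion at 10000: d = +20000, outside the window
  expect_false(flag_te_proximal(mk_gene(30000L, "+"), ins(10000L, "+")))
  # boundary: d = +15000 is inside, +15001 outside
  expect_true(flag_te_proximal(mk_gene(25000L, "+"), ins(10000L, "+")))
  expect_false(flag_te_proximal(mk_gene(25001L, "+"), ins(10000L, "+")))
  # d = -10000 inside, -10001 outside
  expect_true(flag_te_proximal(mk_gene(5000L, "+"), ins(15000L, "+")))
  expect_false(flag_te_proximal(mk_gene(4999L, "+"), ins(15000L, "+")))
  # opposite strands never flag
  expect_false(flag_te_proximal(mk_gene(5000L, "+"), ins(5100L, "-")))
  # '-' gene: the asymmetry flips in genomic coordinates
  expect_true(flag_te_proximal(mk_gene(10000L, "-"), ins(5000L, "-")))
  expect_false(flag_te_proximal(mk_gene(10000L, "-"), ins(26000L, "-")))
  # genomic orientation applies the window in left/right coordinates: a
  # '-' gene 12 kb left of the insertion is inside the window on its own
  # strand but outside it genomically
  expect_true(flag_te_proximal(mk_gene(10000L, "-"), ins(22000L, "-")))
  expect_false(flag_te_proximal(mk_gene(10000L, "-"), ins(22000L, "-"),
                                orientation = "genomic"))
  # TSS inside an insertion is distance 0
  big <- GenomicRanges::GRanges("c", IRanges::IRanges(4000L, 6000L),
                                strand = "+")
  expect_true(flag_te_proximal(mk_gene(5000L, "+"), big))
})

test_that("engineered TE-proximal genes are recovered and enriched", {
  # a gene-rich genome keeps the background proximity rate low enough to
  # detect enrichment among the engineered-proximal set
  b <- simulate_genome(sim_params(genome_length = 1000000L, n_genes = 40L,
                                  n_dispersed_insertions_per_family = 3L,
                                  seed = 19L))
  dispersed <- b$te_insertions[!b$te_insertions$in_cluster]
  flags <- flag_te_proximal(b$genes, dispersed)
  truth <- b$genes$te_proximal_truth
  # every engineered proximal gene is flagged
  expect_true(all(flags[truth]))
  # enrichment of flags among the engineered 'up-regulated' set vs the
  # genome background (one-sided hypergeometric)
  n_up <- sum(truth); k_up <- sum(flags & truth)
  p <- stats::phyper(k_up - 1, sum(flags), sum(!flags), n_up,
                     lower.tail = FALSE)
  expect_lt(p, 0.01)
})

test_that("delta-delta-Ct reproduces its closed forms", {
  mk_ct <- function(tgt_ctrl, tgt_kd, ref = 18) {
    d <- expand.grid(gene = c("mdg1", "rp49"),
                     condition = c("ctrl", "kd"), replicate = 1:3,
                     stringsAsFactors = FALSE)
    d$ct <- ifelse(d$gene == "rp49", ref,
                   ifelse(d$condition == "ctrl", tgt_ctrl, tgt_kd))
    d
  }
  # equal delta-Ct in condition and control: fold 1
  r1 <- ddct(mk_ct(25, 25), reference = "rp49", control = "ctrl")
  expect_equal(r1$fold[r1$condition == "kd"], 1)
  # ddCt = -1 -> fold 2
  r2 <- ddct(mk_ct(25, 24), reference = "rp49", control = "ctrl")
  expect_equal(r2$fold[r2$condition == "kd"], 2)
  # ddCt = +2 -> fold 0.25
  r3 <- ddct(mk_ct(25, 27), reference = "rp49", control = "ctrl")
  expect_equal(r3$fold[r3$condition == "kd"], 0.25)
  # replicate averaging happens on delta-Ct before differencing
  d <- mk_ct(25, 24)
  d$ct[d$gene == "mdg1" & d$condition == "kd"] <- c(23, 24, 25)
  r4 <- ddct(d, "rp49", "ctrl")
  expect_equal(r4$fold[r4$condition == "kd"], 2)
  expect_equal(r4$sd_dct[r4$condition == "kd"], 1)
  # missing reference errors
  bad <- mk_ct(25, 24)
  expect_error(ddct(bad[bad$gene != "rp49", ], "rp49", "ctrl"),
               "reference")
})

test_that("a doubled gene is recovered at log2FC 1 from simulation", {
  b <- small_bundle()
  gid <- b$genes$gene_id
  # the doubled gene is a minor library component, so rpm composition
  # shifts stay well inside the tolerance
  base <- stats::setNames(rep(1000, length(gid)), gid)
  base[gid[1]] <- 100
  doubled <- base; doubled[gid[1]] <- 200
  run <- function(rates, seed) {
    rs <- simulate_cluster_rnaseq(
      b, expression_profile(base_rate = 0.005, gene_rates = rates),
      50L, 40000L, seed = seed)
    asg <- assign_multimappers(exact_align(rs, b), seed = seed)
    list(counts = count_features(asg, b$genes, level = "gene"),
         total = nrow(asg))
  }
  ctrl <- run(base, 201L)
  case <- run(doubled, 202L)
  mat <- feature_count_matrix(list(ctrl = ctrl$counts, case = case$counts),
                              totals = c(ctrl = ctrl$total,
                                         case = case$total))
  fc <- fold_change_table(mat, "case", "ctrl")
  expect_lt(abs(fc$log2fc[fc$feature == gid[1]] - 1), 0.2)
  expect_true(all(abs(fc$log2fc[fc$feature != gid[1]]) < 0.2))
})
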