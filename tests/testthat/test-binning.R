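flam_like <- GenomicRanges::GRanges("chrX", IRanges::IRanges(1, 650972),
                                    strand = "+")

test_that("tiling closed forms match for the flam-sized interval", {
  expect_length(tile_interval(flam_like, 1000L), 650L)
  expect_length(tile_interval(flam_like, 100000L, 1000L, mode = "sliding"),
                551L)
  one <- GenomicRanges::GRanges("c", IRanges::IRanges(11, 110), "+")
  expect_length(tile_interval(one, 100L), 1L)
  expect_length(tile_interval(one, 100L, 100L, mode = "sliding"), 1L)
  expect_warning(empty <- tile_interval(one, 200L, 50L, mode = "sliding"),
                 "shorter")
  expect_length(empty, 0L)
  # trailing partial bin is dropped unless requested
  expect_length(tile_interval(one, 30L), 3L)
  part <- tile_interval(one, 30L, full_bins_only = FALSE)
  expect_length(part, 4L)
  expect_identical(GenomicRanges::width(part)[4], 10L)
})

test_that("bin indices run 5' to 3' in transcriptional order", {
  plus <- tile_interval(GenomicRanges::GRanges("c",
                                               IRanges::IRanges(1, 5000),
                                               "+"), 1000L)
  expect_identical(plus$bin_index, 1:5)
  minus <- tile_interval(GenomicRanges::GRanges("c",
                                                IRanges::IRanges(1, 5000),
                                                "-"), 1000L)
  # genomically first bin is the transcriptional 3' end on the minus strand
  expect_identical(minus$bin_index, 5:1)
})

test_that("counting rules handle containment, boundaries, multimappers", {
  bins <- tile_interval(GenomicRanges::GRanges("c",
                                               IRanges::IRanges(1, 5000),
                                               "+"), 1000L)
  asg <- data.frame(
    read_id = c("in3", "straddle", "multi", "anti", "out"),
    contig = "c",
    start = c(2100L, 990L, 2200L, 2300L, 6000L),
    end = c(2149L, 1039L, 2249L, 2349L, 6049L),
    strand = c("+", "+", "+", "-", "+"),
    width = 50L,
    n_hits = c(1L, 1L, 2L, 1L, 1L), stringsAsFactors = FALSE)
  cnt <- count_bins(asg, bins, unique_only = TRUE, strand = "sense",
                    overlap_rule = "contained")
  expect_identical(as.integer(cnt), c(0L, 0L, 1L, 0L, 0L))
  expect_identical(attr(cnt, "n_ambiguous"), 1L)  # the straddler
  expect_identical(attr(cnt, "n_outside"), 1L)
  # conservation under the contained rule
  expect_identical(sum(cnt) + attr(cnt, "n_ambiguous") +
                     attr(cnt, "n_outside"), attr(cnt, "n_eligible"))
  # strand = both admits the antisense read; unique_only = FALSE the multi
  cnt2 <- count_bins(asg, bins, unique_only = FALSE, strand = "both",
                     overlap_rule = "contained")
  expect_identical(sum(cnt2), 3L)

  # half-overlap: exactly 25 of 50 nt inside the window counts (inclusive)
  win <- GenomicRanges::GRanges("c", IRanges::IRanges(1001, 2000), "+")
  S4Vectors::mcols(win)$bin_index <- 1L
  half <- data.frame(read_id = "h", contig = "c", start = 1976L,
                     end = 2025L, strand = "+", width = 50L, n_hits = 1L,
                     stringsAsFactors = FALSE)
  expect_identical(sum(count_bins(half, win,
                                  overlap_rule = "half_overlap")), 1L)
  # 24 of 50 inside does not count
  half$start <- 1977L; half$end <- 2026L
  expect_identical(sum(count_bins(half, win,
                                  overlap_rule = "half_overlap")), 0L)
})

test_that("rpm normalisation is linear and scale-invariant", {
  expect_equal(rpm_normalize(50, 1e6), 50)
  expect_equal(rpm_normalize(0, 1e6), 0)
  expect_equal(rpm_normalize(c(2, 4), 2e6), rpm_normalize(c(4, 8), 4e6))
  expect_error(rpm_normalize(5, 0), "positive")
})

test_that("fold-change rule variants apply their pseudo-counts and discards", {
  rpm <- cbind(ctrl = c(2, 0, 5, 0, 3), kd = c(4, 1, 0, 0, 3),
               kd2 = c(1, 0, 2, 1, 3))
  # sliding_100kb: pc = 1, no discard; 4 vs 2 rpm -> log2(5/3)
  fc <- bin_log2fc(rpm, "kd", "ctrl", fc_variant("sliding_100kb"))
  expect_true(all(fc$keep))
  expect_equal(fc$log2fc[1], log2(5 / 3))
  # identity: case = control gives 0 for every kept bin, any variant
  for (v in c("osc_1kb", "ovary_1kb", "sliding_100kb")) {
    same <- cbind(a = c(1, 2, 3), b = c(1, 2, 3))
    f0 <- bin_log2fc(same, "a", "b", fc_variant(v))
    expect_equal(f0$log2fc[f0$keep], rep(0, sum(f0$keep)))
  }
  # osc_1kb: a bin with 0 rpm in more than one sample is discarded
  fosc <- bin_log2fc(rpm, "kd", "ctrl", fc_variant("osc_1kb"))
  expect_identical(fosc$keep, c(TRUE, FALSE, TRUE, FALSE, TRUE))
  expect_identical(fosc$reason[2], "zero_in_gt1_sample")
  # a single zero is kept, with the 0.01 pseudo-count keeping FC finite
  expect_equal(fosc$log2fc[3], log2(0.01 / 5.01))
  # ovary_1kb: bins at 0 rpm only in the control are discarded
  fov <- bin_log2fc(rpm, "kd", "ctrl", fc_variant("ovary_1kb"))
  expect_false(fov$keep[2])   # ctrl 0, kd 1
  expect_true(fov$keep[4])    # 0 in both: not "only in the control"
  expect_identical(fov$reason[2], "zero_only_in_control")
  # custom variant validation
  expect_error(fc_variant("custom"), "custom")
})

test_that("the positional gradient summarises monotone and flat profiles", {
  dec <- data.frame(bin_index = 1:20, log2fc = seq(0, -2, length.out = 20))
  g <- positional_gradient(dec)
  expect_equal(g$rho, -1)
  expect_lt(g$p_value, 1e-3)
  expect_lt(g$slope, 0)
  flat <- data.frame(bin_index = 1:20, log2fc = rep(0.5, 20))
  gf <- positional_gradient(flat)
  expect_equal(gf$rho, 0)
  expect_equal(gf$slope, 0)
  expect_warning(gm <- positional_gradient(dec[1:5, ]), "fewer than 10")
  expect_true(is.na(gm$rho))
})

test_that("replicate pooling preserves counts and rpm algebra", {
  a <- stats::setNames(c(10, 20, 30), paste0("b", 1:3))
  p1 <- pool_replicates(list(a, a), totals = c(100, 100))
  expect_identical(p1$counts, a * 2)
  expect_equal(rpm_normalize(p1$counts, p1$total), rpm_normalize(a, 100))
  # single replicate is the identity
  expect_identical(pool_replicates(list(a), 100)$counts, a)
  # pooled rpm equals the count-weighted combination of replicate rpms
  b <- stats::setNames(c(5, 0, 45), paste0("b", 1:3))
  pooled <- pool_replicates(list(a, b), totals = c(100, 400))
  lhs <- rpm_normalize(pooled$counts, pooled$total)
  rhs <- (rpm_normalize(a, 100) * 100 + rpm_normalize(b, 400) * 400) / 500
  expect_equal(lhs, rhs)
  expect_error(pool_replicates(list(a, b[1:2]), c(1, 1)), "mismatched")
})

test_that("uniform up-regulation yields flat log2FC near 1 and decay a negative gradient", {
  b <- small_bundle()
  track <- kmer_uniqueness_track(b, k = 45L)
  # 500 bp bins give enough datapoints on the 10 kb toy cluster
  bins <- filter_by_mappability(tile_interval(b$cluster, 500L), track, 0.8)
  # genes absorb most of the library so that cluster rpm can rise; the
  # cluster is ~10 percent of mapped reads in the control here
  grates <- stats::setNames(rep(300, length(b$genes)), b$genes$gene_id)
  run <- function(profile, seed) {
    rs <- simulate_cluster_rnaseq(b, profile, 50L, 30000L, seed = seed)
    asg <- assign_multimappers(exact_align(rs, b), seed = seed)
    list(counts = count_bins(asg, bins), total = nrow(asg))
  }
  ctrl <- run(expression_profile(gene_rates = grates), 101L)
  zuc <- run(expression_profile(scale = 2, gene_rates = grates), 102L)
  nup <- run(expression_profile(decay = 1.5, gene_rates = grates), 103L)
  rpm <- cbind(ctrl = rpm_normalize(ctrl$counts, ctrl$total),
               zuc = rpm_normalize(zuc$counts, zuc$total),
               nup = rpm_normalize(nup$counts, nup$total))
  fz <- bin_log2fc(rpm[, c("ctrl", "zuc")], "zuc", "ctrl",
                   fc_variant("osc_1kb"), bin_index = bins$bin_index)
  # doubled cluster rate: near-uniform ~2x up-regulation (slightly under 2
  # because rpm renormalises against the whole library) with no gradient
  expect_lt(abs(stats::median(fz$log2fc[fz$keep]) - 1), 0.25)
  expect_gt(positional_gradient(fz)$p_value, 0.01)
  fn <- bin_log2fc(rpm[, c("ctrl", "nup")], "nup", "ctrl",
                   fc_variant("osc_1kb"), bin_index = bins$bin_index)
  gn <- positional_gradient(fn)
  expect_lt(gn$rho, 0)
  expect_lt(gn$p_value, 1e-3)
  # window-size robustness: sliding windows agree on the gradient sign
  wins <- filter_by_mappability(
    tile_interval(b$cluster, 3000L, 500L, mode = "sliding"),
    kmer_uniqueness_track(b, k = 50L), 0.05)
  run_w <- function(rs_seed, profile) {
    rs <- simulate_cluster_rnaseq(b, profile, 50L, 30000L, seed = rs_seed)
    asg <- assign_multimappers(exact_align(rs, b), seed = rs_seed)
    cw <- count_bins(asg, wins, overlap_rule = "half_overlap")
    rpm_normalize(cw, sum(asg$n_hits == 1L))
  }
  rpmw <- cbind(ctrl = run_w(101L, expression_profile(gene_rates = grates)),
                nup = run_w(103L, expression_profile(decay = 1.5,
                                                     gene_rates = grates)))
  fw <- bin_log2fc(rpmw, "nup", "ctrl", fc_variant("sliding_100kb"),
                   bin_index = wins$bin_index)
  gw <- positional_gradient(fw)
  expect_identical(sign(gw$rho), sign(gn$rho))
})
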