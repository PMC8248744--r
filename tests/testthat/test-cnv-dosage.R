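test_that("size factors implement median-of-ratios", {
  # hand computation: geometric means (14.142, 28.284, 42.426); every
  # per-gene ratio is 1/sqrt(2) for s1 and sqrt(2) for s2
  m <- cbind(s1 = c(10, 20, 30), s2 = c(20, 40, 60))
  sf <- size_factors(m)
  expect_equal(unname(sf), c(1 / sqrt(2), sqrt(2)), tolerance = 1e-6)

  # identical samples give unit factors
  same <- cbind(a = c(5, 50, 500), b = c(5, 50, 500))
  expect_equal(unname(size_factors(same)), c(1, 1))

  # scale equivariance: multiplying one sample's counts by c multiplies
  # its factor by c relative to the other samples (the geometric-mean
  # reference absorbs a common rescaling)
  set.seed(1)
  counts <- matrix(rpois(200, 50), 50, 4,
                   dimnames = list(NULL, paste0("s", 1:4)))
  sf1 <- size_factors(counts)
  scaled <- counts
  scaled[, 2] <- scaled[, 2] * 3L
  sf2 <- size_factors(scaled)
  expect_equal(unname((sf2[2] / sf2[1]) / (sf1[2] / sf1[1])), 3,
               tolerance = 1e-9)

  expect_error(size_factors(matrix(c(0, 1, 1, 0), 2, 2)), "all-positive")
})

test_that("size factors agree with the established median-of-ratios implementation", {
  skip_if_not_installed("DESeq2")
  set.seed(2)
  counts <- matrix(rnbinom(600, mu = 80, size = 5), 100, 6,
                   dimnames = list(sprintf("g%03d", 1:100), paste0("s", 1:6)))
  counts[counts == 0] <- 1L
  ours <- size_factors(counts)
  theirs <- DESeq2::estimateSizeFactorsForMatrix(counts)
  expect_equal(unname(ours), unname(theirs), tolerance = 1e-8)
})

test_that("relative coverage is baseline-anchored and library-size invariant", {
  set.seed(3)
  base_depth <- 100
  counts <- matrix(rpois(5 * 4, base_depth), 5, 4,
                   dimnames = list(paste0("g", 1:5), c("c1", "c2", "t1", "t2")))
  # triplicate gene 3 in the test samples at equal sequencing depth
  counts[3, c("t1", "t2")] <- rpois(2, 3 * base_depth)
  sf <- rep(1, 4); names(sf) <- colnames(counts)
  rel <- relative_coverage(counts, sf, c("c1", "c2"))
  expect_equal(mean(rel[3, c("t1", "t2")]), 3, tolerance = 0.3)
  # baseline samples sit near 1 by construction
  expect_equal(unname(rowMeans(rel[, c("c1", "c2")])), rep(1, 5),
               tolerance = 1e-12)

  # doubling a sample's library size leaves relative coverage unchanged
  doubled <- counts
  doubled[, "t1"] <- doubled[, "t1"] * 2L
  rel2 <- relative_coverage(doubled, size_factors(doubled), c("c1", "c2"))
  rel1 <- relative_coverage(counts, size_factors(counts), c("c1", "c2"))
  expect_equal(rel2[, "t1"], rel1[, "t1"], tolerance = 1e-9)
})

test_that("CNV segment calling finds maximal gain runs", {
  annotation <- data.frame(gene_id = sprintf("g%02d", 1:20),
                           chrom = rep("2", 20),
                           start = (0:19) * 3000 + 1)
  annotation$end <- annotation$start + 1999

  # uniform single-copy coverage: no segments
  flat <- setNames(rep(1, 20), annotation$gene_id)
  expect_identical(nrow(call_cnv_segments(flat, annotation)), 0L)

  # five consecutive genes near 3x flanked by 1x: one segment, copies 3
  rel <- flat
  rel[8:12] <- c(2.9, 3.1, 3.0, 2.95, 3.05)
  segs <- call_cnv_segments(rel, annotation)
  expect_identical(nrow(segs), 1L)
  expect_identical(segs$n_genes, 5L)
  expect_identical(segs$copies, 3L)
  expect_identical(segs$start, annotation$start[8])
  expect_identical(segs$end, annotation$end[12])
  expect_identical(segs$genes, paste(annotation$gene_id[8:12], collapse = ","))

  # per-gene threshold decisions equal a brute-force run scan
  set.seed(4)
  rnd <- setNames(runif(20, 0.5, 3.5), annotation$gene_id)
  segs2 <- call_cnv_segments(rnd, annotation, gain_threshold = 1.5)
  gain <- rnd >= 1.5
  runs <- rle(unname(gain))
  expect_identical(nrow(segs2), sum(runs$values))
  expect_equal(sum(segs2$n_genes), sum(gain))
})

test_that("qPCR copy number inverts the efficiency model", {
  # closed form: E = 2 both amplicons, target Ct lower by log2(3)
  qpcr <- data.frame(
    sample = rep(c("calibrator", "s1"), each = 4),
    amplicon = rep(rep(c("target", "reference"), each = 2), 2),
    replicate = rep(1:2, 4),
    ct = c(30, 30, 25, 25, 30 - log2(3), 30 - log2(3), 25, 25))
  cn <- qpcr_copy_number(qpcr, efficiency = c(target = 2, reference = 2))
  expect_equal(cn[["s1"]], 3, tolerance = 1e-12)
  expect_equal(cn[["calibrator"]], 1, tolerance = 1e-12)

  # noiseless simulator Cts for true copies {1, 2, 3} invert exactly for
  # any efficiency in (1, 2]
  cfg <- tiny_config(seed = 20)
  cfg$qpcr$sd <- 0
  tab <- emit_qpcr(c(calibrator = 1, a = 2, b = 3), cfg)
  cn2 <- qpcr_copy_number(tab)
  expect_equal(cn2[["a"]], 2, tolerance = 1e-10)
  expect_equal(cn2[["b"]], 3, tolerance = 1e-10)
  expect_equal(cn2[["calibrator"]], 1, tolerance = 1e-10)

  expect_error(qpcr_copy_number(tab, efficiency = c(target = 2.5, reference = 2)),
               "\\(1, 2\\]")
  expect_error(qpcr_copy_number(tab, calibrator = "nope"), "calibrator")
})

test_that("expression fold change is the ratio of normalized group means", {
  set.seed(5)
  counts <- matrix(rpois(40, 100), 10, 4,
                   dimnames = list(paste0("g", 1:10),
                                   c("a1", "a2", "b1", "b2")))
  sf <- rep(1, 4); names(sf) <- colnames(counts)
  expect_error(expression_fold_change(counts, sf, c("a1", "a2"), c("a1", "b1")),
               "disjoint")

  scaled <- counts
  scaled[4, c("a1", "a2")] <- counts[4, c("a1", "a2")] * 5L
  fc <- expression_fold_change(scaled, sf, c("a1", "a2"), c("b1", "b2"))
  base <- expression_fold_change(counts, sf, c("a1", "a2"), c("b1", "b2"))
  expect_equal(fc[["g4"]] / base[["g4"]], 5, tolerance = 1e-12)

  # two groups with identical count profiles have unit fold change
  dup <- counts
  dup[, c("b1", "b2")] <- counts[, c("a1", "a2")]
  ident <- expression_fold_change(dup, sf, c("a1", "a2"), c("b1", "b2"))
  expect_equal(unname(ident), rep(1, 10))
})

test_that("DNA coverage ratio and RNA fold change agree for pure dosage genes", {
  # selected populations near-fixed for a 3-copy block; no cis-eQTL on the
  # CNV chromosome, so expression scales with copy number alone
  cfg <- sim_config(
    chromosome_lengths = c(8e5, 5e5, 3e5),
    n_pairs = 3L, n_females = 200L, n_generations = 20L,
    causal_loci = data.frame(chrom = 2L, pos = 2.5e5, s = 0.5, h = 0.1),
    cnv_locus = list(chrom = 2L, start = 249001, end = 263000, copies = 3L),
    cis_eqtl = NULL,
    dna_depth_mean = 150, rna_depth_mean = 300, nb_dispersion = 0.02,
    seed = 21L)
  sim <- simulate_experiment(cfg)
  cnv_genes <- sim$truth$cnv_genes
  sel <- sim$pairs$selected
  ctl <- sim$pairs$control

  dna_rel <- relative_coverage(sim$dna_gene_counts,
                               size_factors(sim$dna_gene_counts), ctl)
  dna_ratio <- mean(rowMeans(dna_rel[cnv_genes, sel, drop = FALSE]))
  rna_fc <- mean(expression_fold_change(sim$rna_gene_counts,
                                        size_factors(sim$rna_gene_counts),
                                        sel, ctl)[cnv_genes])
  # locus-level estimates (mean over the five member genes, as the CNV
  # caller reports them) agree within 15%
  expect_lt(abs(rna_fc / dna_ratio - 1), 0.15)
  # both reflect the underlying ~3:1 dosage (controls keep one-copy
  # haplotypes segregating, so the contrast is below the full 3)
  expect_gt(dna_ratio, 1.3)
})
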