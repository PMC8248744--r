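test_that("circularize concatenates chromosomes and round-trips", {
  chrom <- rep(c("1", "2", "3"), each = 26)
  vals <- seq_len(78) / 100
  track <- make_track(vals, chrom = chrom)
  ring <- circularize(track)
  expect_identical(nrow(ring$values), 78L)
  # ring order is the linear grid order: chr3's last window precedes chr1's
  # first window around the circle
  expect_identical(ring$index, 1:78)
  expect_equal(decircularize(ring, ring$mean), track$mean)

  # missing windows are removed with positions remembered
  vals[c(5, 40)] <- NA
  track2 <- make_track(vals, chrom = chrom)
  ring2 <- circularize(track2)
  expect_identical(nrow(ring2$values), 76L)
  back <- decircularize(ring2, ring2$mean)
  expect_true(all(is.na(back[c(5, 40)])))
  expect_equal(back[-c(5, 40)], track2$mean[-c(5, 40)])

  empty <- make_track(rep(NA_real_, 5))
  expect_error(circularize(empty), "empty track")
})

test_that("permutation null is exact for degenerate rings", {
  zero <- circularize(make_track(rep(0, 50)))
  null0 <- permutation_null(zero, permutation_params(100, 0.05, seed = 1))
  expect_true(all(null0$maxima == 0))
  expect_identical(null0$threshold, 0)

  # a constant ring is invariant under rotation: every maximum equals |c|,
  # so the multiset of ring values is preserved by each rotation
  const <- circularize(make_track(rep(-0.3, 50)))
  nullc <- permutation_null(const, permutation_params(200, 0.05, seed = 2))
  expect_true(all(abs(nullc$maxima - 0.3) < 1e-12))
  expect_equal(nullc$threshold, 0.3)
})

test_that("threshold is calibrated on independent-noise rings and monotone in the level", {
  set.seed(33)
  n_win <- 200
  n_pairs <- 11
  sigma <- 0.1
  vals <- matrix(rnorm(n_win * n_pairs, 0, sigma), n_win, n_pairs)
  track <- structure(list(
    grid = data.frame(chrom = "1", start = seq(1, by = 5000, length.out = n_win),
                      end = seq(75000, by = 5000, length.out = n_win)),
    values = vals, mean = rowMeans(vals),
    n_pairs_used = rep(n_pairs, n_win)), class = "paired_diff_track")
  ring <- circularize(track)
  null <- permutation_null(ring, permutation_params(1000, 0.1, seed = 3))

  # fresh independent draws from the same null: the genome-wide exceedance
  # rate of the threshold matches the level
  n_mc <- 400
  exceed <- vapply(seq_len(n_mc), function(i) {
    m <- rowMeans(matrix(rnorm(n_win * n_pairs, 0, sigma), n_win, n_pairs))
    max(abs(m)) >= null$threshold
  }, logical(1))
  rate <- mean(exceed)
  expect_lt(abs(rate - 0.1), 3 * sqrt(0.1 * 0.9 / n_mc) + 0.02)

  # threshold decreases as the level grows
  th <- vapply(c(0.01, 0.05, 0.2),
               function(f) permutation_null(ring, permutation_params(1000, f, seed = 4))$threshold,
               numeric(1))
  expect_true(all(diff(th) <= 0))
})

test_that("QTL calls are maximal significant runs that never span chromosomes", {
  chrom <- rep(c("1", "2"), each = 20)
  vals <- rep(0.05, 40)
  vals[8:12] <- c(0.3, 0.35, 0.4, 0.35, 0.3)   # run on chr1, peak at 10
  vals[20] <- 0.3                               # last window of chr1
  vals[21] <- 0.3                               # first window of chr2
  vals[30] <- -0.45                             # isolated negative peak
  track <- make_track(vals, chrom = chrom)

  calls <- call_qtls(track, 0.3)
  expect_identical(nrow(calls), 4L)
  # adjacent significant windows on different chromosomes are two calls
  expect_identical(calls$run_first, c(8L, 20L, 21L, 30L))
  expect_identical(calls$run_last, c(12L, 20L, 21L, 30L))
  expect_identical(calls$peak_row, c(10L, 20L, 21L, 30L))
  # negative deviations count by absolute value
  expect_equal(calls$peak_value[4], -0.45)

  # leftmost tie-break at the peak
  tie <- make_track(c(0.05, 0.4, 0.4, 0.05))
  expect_identical(call_qtls(tie, 0.3)$peak_row, 2L)

  expect_identical(nrow(call_qtls(track, 0.99)), 0L)
})

test_that("interval walk follows the peak-similarity block rule", {
  # flat plateau at the peak value spans the whole plateau
  vals <- c(rep(0, 5), rep(0.4, 7), rep(0, 8))
  track <- make_track(vals)
  call <- call_qtls(track, 0.3)
  iv <- qtl_interval(track, call[1, ], interval_params(0.005, 5))
  expect_identical(attr(iv, "rows"), 6:12)
  expect_identical(iv$start, track$grid$start[6])
  expect_identical(iv$end, track$grid$end[12])

  # isolated peak: all neighbours dissimilar, walk stops immediately
  spike <- make_track(c(rep(0, 7), 0.5, rep(0, 12)))
  call2 <- call_qtls(spike, 0.4)
  iv2 <- qtl_interval(spike, call2[1, ], interval_params(0.005, 5))
  expect_identical(attr(iv2, "rows"), 8:8)

  # gap of four dissimilar windows (< block_len) is bridged: peak 0.312 at
  # window 8, peak-similar 0.309 at window 3, windows 4-7 dissimilar
  vals3 <- c(0.1, 0.1, 0.309, 0.2, 0.2, 0.2, 0.2, 0.312, rep(0.1, 7))
  track3 <- make_track(vals3)
  call3 <- call_qtls(track3, 0.31)
  expect_identical(call3$peak_row, 8L)
  iv3 <- qtl_interval(track3, call3[1, ], interval_params(0.005, 5))
  expect_identical(attr(iv3, "rows"), 3:8)

  # a gap of block_len dissimilar windows stops the walk
  vals4 <- c(0.309, 0.2, 0.2, 0.2, 0.2, 0.2, 0.312, rep(0.1, 8))
  track4 <- make_track(vals4)
  call4 <- call_qtls(track4, 0.31)
  iv4 <- qtl_interval(track4, call4[1, ], interval_params(0.005, 5))
  expect_identical(attr(iv4, "rows"), 7:7)
})

test_that("DEG counting matches a brute-force overlap scan", {
  set.seed(21)
  n_genes <- 300
  annotation <- data.frame(
    gene_id = sprintf("g%03d", seq_len(n_genes)),
    chrom = sample(c("1", "2"), n_genes, replace = TRUE),
    start = sample.int(9e5, n_genes))
  annotation$end <- annotation$start + sample.int(5000, n_genes)
  de <- data.frame(gene_id = annotation$gene_id,
                   fc = runif(n_genes, -6, 6),
                   padj = runif(n_genes))
  intervals <- data.frame(chrom = c("1", "2"),
                          start = c(2e5, 5e5), end = c(3e5, 6e5))
  res <- count_degs_in_intervals(de, annotation, intervals)

  is_deg <- abs(de$fc) >= 2 & de$padj <= 0.05
  brute <- vapply(seq_len(nrow(intervals)), function(i) {
    sum(is_deg & annotation$chrom == intervals$chrom[i] &
          annotation$start <= intervals$end[i] &
          annotation$end >= intervals$start[i])
  }, numeric(1))
  expect_equal(res$per_interval, as.integer(brute))
  expect_identical(res$n_deg, sum(is_deg))

  # trivial cases
  empty <- count_degs_in_intervals(de[0, ], annotation, intervals)
  expect_identical(empty$total, 0L)
  one_in <- count_degs_in_intervals(
    data.frame(gene_id = c("a", "b"), fc = c(5, 5), padj = c(0.01, 0.01)),
    data.frame(gene_id = c("a", "b"), chrom = "1",
               start = c(250000, 700000), end = c(251000, 701000)),
    intervals[1, , drop = FALSE])
  expect_identical(one_in$per_interval, 1L)
  expect_identical(one_in$total, 1L)

  dup <- de[c(1, 1), ]
  expect_error(count_degs_in_intervals(dup, annotation, intervals),
               "duplicate")
})

test_that("simulated selection at three loci yields three localized QTL", {
  # moderate-size genome keeps this fast; loci well separated
  cfg <- sim_config(
    chromosome_lengths = c(3e6, 2e6, 1e6),
    n_pairs = 8L, n_females = 300L, n_generations = 25L,
    causal_loci = data.frame(chrom = c(1L, 1L, 2L),
                             pos = c(7e5, 2.3e6, 1e6),
                             s = 0.2, h = 0.1),
    # CNV neutral here: this test isolates the three-locus call geometry
    cnv_locus = list(chrom = 2L, start = 999001, end = 1013000, copies = 3L),
    cnv_cost = 0,
    cis_eqtl = data.frame(chrom = 1L, pos = 7e5, multiplier = 2.25),
    seed = 17L)
  wf <- bsa_qtl_workflow(cfg, perm = permutation_params(500, 0.05, seed = 170))
  expect_identical(nrow(wf$calls), 3L)
  truth <- cfg$causal_loci
  for (i in seq_len(3)) {
    mid <- (wf$calls$peak_start[i] + wf$calls$peak_end[i]) / 2
    on_chr <- truth$pos[truth$chrom == as.integer(wf$calls$chrom[i])]
    expect_lt(min(abs(mid - on_chr)), 150000)
    # selection favors the resistant-parent allele: peaks are positive
    expect_gt(wf$calls$peak_value[i], 0)
  }
  # each interval contains its peak
  for (i in seq_len(3)) {
    expect_lte(wf$intervals$start[i], wf$calls$peak_start[i])
    expect_gte(wf$intervals$end[i], wf$calls$peak_end[i])
  }
})
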