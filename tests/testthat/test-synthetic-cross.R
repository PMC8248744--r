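test_that("founders: transmitted-allele ground truth follows the cross design", {
  cfg <- tiny_config(seed = 1)
  f <- make_founders(cfg)
  sites <- f$sites

  # the inbred mother is homozygous reference everywhere
  expect_true(all(sites$mother_allele == 0L))
  # strain-homozygous-alternate sites are always informative
  hom <- sites$strain_genotype == "1/1"
  expect_true(all(sites$informative[hom]))
  expect_true(all(sites$male_allele[hom] == 1L))
  # informative <=> male allele differs from the maternal allele
  expect_identical(sites$informative, sites$male_allele != sites$mother_allele)

  # the single male is one random gamete: about half of the strain's
  # heterozygous sites are informative (binomial expectation)
  het <- sites$strain_genotype == "0/1"
  p_hat <- mean(sites$informative[het])
  se <- sqrt(0.5 * 0.5 / sum(het))
  expect_lt(abs(p_hat - 0.5), 3 * se)
})

test_that("simulation output is byte-identical under a fixed seed", {
  cfg <- tiny_config(seed = 5, n_pairs = 2L, n_generations = 4L)
  a <- simulate_experiment(cfg)
  b <- simulate_experiment(cfg)
  expect_identical(a$dna_sites$alt, b$dna_sites$alt)
  expect_identical(a$rna_gene_counts, b$rna_gene_counts)
  expect_identical(a$qpcr$ct, b$qpcr$ct)
  expect_identical(a$truth$copies_true, b$truth$copies_true)
})

test_that("neutral drift keeps the replicate-mean transmitted-allele frequency at 1/2", {
  cfg <- tiny_config(seed = 3, s = 0, n_pairs = 4L, n_generations = 15L,
                     n_females = 120L)
  f <- make_founders(cfg)
  pop_means <- unlist(lapply(seq_len(cfg$n_pairs), function(pr) {
    pair <- run_pair(f, cfg, pr)
    c(mean(female_allele_freq(pair$selected)),
      mean(female_allele_freq(pair$control)))
  }))
  se <- sd(pop_means) / sqrt(length(pop_means))
  expect_lt(abs(mean(pop_means) - 0.5), 3 * se)
})

test_that("strong recessive selection drives the causal locus to near-fixation", {
  cfg <- tiny_config(seed = 2, s = 0.9, h = 0, n_pairs = 1L,
                     n_generations = 35L)
  f <- make_founders(cfg)
  pair <- run_pair(f, cfg, 1L)
  freq_sel <- female_allele_freq(pair$selected)[f$map$causal_idx]
  expect_gt(freq_sel, 0.95)
  # the unselected sister population stays intermediate
  freq_ctl <- female_allele_freq(pair$control)[f$map$causal_idx]
  expect_lt(freq_ctl, 0.95)
})

test_that("selected-pool causal frequency is non-decreasing in the selection coefficient", {
  freqs <- vapply(c(0, 0.3, 0.6), function(s) {
    cfg <- tiny_config(seed = 4, s = s, n_pairs = 2L, n_generations = 12L)
    f <- make_founders(cfg)
    mean(vapply(1:2, function(pr) {
      if (s > 0) {
        female_allele_freq(run_pair(f, cfg, pr)$selected)[f$map$causal_idx]
      } else {
        idx <- site_nearest_test(f$map, 2L, 2.5e5)
        female_allele_freq(run_pair(f, cfg, pr)$selected)[idx]
      }
    }, numeric(1)))
  }, numeric(1))
  expect_true(all(diff(freqs) >= 0))
})

test_that("pooled reads are binomial draws at the pooled allele frequency", {
  cfg <- tiny_config(seed = 6)
  f <- make_founders(cfg)
  st <- init_population(f, cfg)  # F1 females: frequency exactly 0.5

  set.seed(11)
  reads <- emit_pool_reads(st, f, cfg, depth_mean = 100)
  inf <- f$sites$informative
  frac <- sum(reads$alt[inf]) / sum(reads$ref[inf] + reads$alt[inf])
  expect_lt(abs(frac - 0.5), 0.01)
  expect_true(all(reads$ref >= 0 & reads$alt >= 0))

  # frequency 0 at every site -> no alternate reads at any depth
  st0 <- st
  st0$female_h2 <- st0$female_h1
  set.seed(12)
  reads0 <- emit_pool_reads(st0, f, cfg)
  expect_true(all(reads0$alt == 0))
})

test_that("fixed CNV inflates per-gene DNA coverage by the copy number", {
  cfg <- tiny_config(seed = 7, s = 0.9, h = 0, n_pairs = 1L,
                     n_generations = 25L, dna_depth_mean = 200)
  sim <- simulate_experiment(cfg)
  cnv <- sim$truth$cnv_genes
  expect_length(cnv, 5L)
  flank <- setdiff(sim$annotation$gene_id[sim$annotation$chrom == 2], cnv)
  ratio <- mean(sim$dna_gene_counts[cnv, "R1"]) /
    mean(sim$dna_gene_counts[flank, "R1"])
  # selected population is near-fixed for the 3-copy haplotype
  expect_lt(abs(ratio - 3), 0.25)
})

test_that("qPCR emission follows the efficiency model exactly when noiseless", {
  cfg <- tiny_config(seed = 8)
  cfg$qpcr$sd <- 0
  tab <- emit_qpcr(c(a = 1, b = 3), cfg)
  ct <- tapply(tab$ct, paste(tab$sample, tab$amplicon), mean)
  # tripling the copy number lowers the target Ct by exactly log_E(3)
  expect_equal(ct[["a target"]] - ct[["b target"]],
               log(3) / log(cfg$qpcr$E_target), tolerance = 1e-12)
  # the single-copy reference amplicon is copy-number independent
  expect_equal(ct[["a reference"]], ct[["b reference"]], tolerance = 1e-12)
  # equal copies give identical Cts across replicates when sd = 0
  tab2 <- emit_qpcr(c(x = 2, y = 2), cfg)
  expect_equal(length(unique(tab2$ct[tab2$amplicon == "target"])), 1L)

  # replicate noise has the configured standard deviation
  cfg$qpcr$sd <- 0.1
  set.seed(20)
  many <- emit_qpcr(setNames(rep(1, 500), paste0("s", 1:500)), cfg)
  expect_lt(abs(sd(many$ct[many$amplicon == "reference"]) - 0.1), 0.01)

  expect_error(emit_qpcr(c(a = 0), cfg), "positive")
})

test_that("dose-response emission mixes probit curves", {
  cfg <- tiny_config(seed = 9)
  # at the class LC50 mortality is one half
  lc50_s <- 10^cfg$dose_response$log10_lc50[cfg$dose_response$genotype == "S"]
  set.seed(31)
  tab <- emit_dose_response(data.frame(genotype = "S", proportion = 1),
                            cfg, lc50_s, 20000L)
  expect_lt(abs(tab$dead / tab$n - 0.5), 3 * sqrt(0.25 / 20000))

  # a 50:50 mixture lies between the pure curves
  dose <- 50
  p_class <- vapply(c("S", "R"), function(g) {
    row <- cfg$dose_response[cfg$dose_response$genotype == g, ]
    pnorm(row$slope * (log10(dose) - row$log10_lc50))
  }, numeric(1))
  set.seed(32)
  mix <- emit_dose_response(data.frame(genotype = c("S", "R"),
                                       proportion = c(0.5, 0.5)),
                            cfg, dose, 20000L)
  p_mix <- mix$dead / mix$n
  expect_gt(p_mix, min(p_class))
  expect_lt(p_mix, max(p_class))

  expect_error(emit_dose_response(data.frame(genotype = "S", proportion = 1),
                                  cfg, c(-1, 10), 100L), "positive")
  expect_error(emit_dose_response(data.frame(genotype = "S", proportion = 0.8),
                                  cfg, 10, 100L), "sum to 1")
})

test_that("advance_generation preserves ploidy structure and census size", {
  cfg <- tiny_config(seed = 10, n_generations = 3L)
  f <- make_founders(cfg)
  set.seed(1)
  st <- init_population(f, cfg, "selected")
  st2 <- advance_generation(st, cfg)
  expect_identical(ncol(st2$female_h1), cfg$n_females)
  expect_identical(ncol(st2$female_h2), cfg$n_females)
  expect_identical(ncol(st2$male_h), cfg$n_females)
  expect_identical(st2$generation, 1L)
  # alleles stay binary
  expect_true(all(as.integer(st2$female_h1) %in% 0:1))
})
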