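#' Tiled gene annotation for the toy genome
#'
#' Genes of fixed length tile each chromosome at a regular spacing, so the
#' default copy-number-variable block spans exactly five consecutive genes.
#'
#' @param config A [sim_config()].
#' @return data.frame with `gene_id`, `chrom`, `start`, `end`
#'   (1-based inclusive coordinates).
#' @export
gene_annotation <- function(config) {
  per_chrom <- lapply(seq_along(config$chromosome_lengths), function(ci) {
    len <- config$chromosome_lengths[ci]
    starts <- seq(1, len - config$gene_length + 1, by = config$gene_spacing)
    data.frame(chrom = ci, start = starts,
               end = starts + config$gene_length - 1L)
  })
  ann <- do.call(rbind, per_chrom)
  ann$gene_id <- sprintf("gene%05d", seq_len(nrow(ann)))
  ann[, c("gene_id", "chrom", "start", "end")]
}

# Pooled allele counts container: a site table plus ref/alt count matrices
# with one column per sample.
pool_counts <- function(sites, ref, alt) {
  stopifnot(nrow(sites) == nrow(ref), identical(dim(ref), dim(alt)))
  structure(list(sites = sites, ref = ref, alt = alt,
                 samples = colnames(ref)),
            class = "pool_counts")
}

#' @export
print.pool_counts <- function(x, ...) {
  cat(sprintf("<pool_counts> %d sites x %d samples\n",
              nrow(x$sites), length(x$samples)))
  invisible(x)
}

#' Emit pooled sequencing reads for one population
#'
#' Pools up to `pool_size` females; per-site read depth is Poisson with the
#' configured mean and the alternate-allele read count is binomial at the
#' pooled frequency of the non-maternal allele (zero at sites where the
#' sire transmitted the maternal allele).
#'
#' @param state A `population_state` (final generation).
#' @param founders The [make_founders()] result (supplies the full site table).
#' @param config A [sim_config()].
#' @param depth_mean Mean read depth (defaults to `config$dna_depth_mean`).
#' @param freq Optional precomputed pooled frequency over all sites (as
#'   returned by [pooled_site_freq()]); drawn from the state when missing.
#' @return data.frame `chrom`, `pos`, `ref`, `alt` over all sites.
#' @export
emit_pool_reads <- function(state, founders, config,
                            depth_mean = config$dna_depth_mean,
                            freq = NULL) {
  if (is.null(freq)) freq <- pooled_site_freq(state, founders, config)
  sites <- founders$sites
  depth <- rpois(nrow(sites), depth_mean)
  alt <- rbinom(nrow(sites), depth, freq)
  data.frame(chrom = sites$chrom, pos = sites$pos,
             ref = depth - alt, alt = alt)
}

#' @rdname emit_pool_reads
#' @export
pooled_site_freq <- function(state, founders, config) {
  n_pool <- min(config$pool_size, ncol(state$female_h1))
  idx <- if (n_pool < ncol(state$female_h1)) {
    sample.int(ncol(state$female_h1), n_pool)
  } else {
    seq_len(ncol(state$female_h1))
  }
  p_inf <- (rowSums(state$female_h1[, idx, drop = FALSE] != as.raw(0)) +
              rowSums(state$female_h2[, idx, drop = FALSE] != as.raw(0))) /
    (2 * n_pool)
  p <- numeric(nrow(founders$sites))
  p[founders$map$site_row] <- p_inf
  p
}

# Population-level dosage summaries at the informative site nearest to a
# given bp position: mean multiplier^dose and mean copy ratio over females.
site_nearest <- function(map, chrom, pos) {
  on_chr <- which(map$chrom == chrom)
  if (!length(on_chr)) stop("no informative site on chromosome ", chrom)
  on_chr[which.min(abs(map$pos[on_chr] - pos))]
}

mean_cis_factor <- function(state, idx, multiplier) {
  dose <- as.integer(state$female_h1[idx, ]) + as.integer(state$female_h2[idx, ])
  mean(multiplier^dose)
}

mean_copy_ratio <- function(state, idx, copies) {
  dose <- as.integer(state$female_h1[idx, ]) + as.integer(state$female_h2[idx, ])
  mean((dose * copies + (2 - dose)) / 2)
}

# Per-gene expected-coverage multipliers for one population: the product of
# the local copy-number ratio (CNV genes) and the cis-eQTL expression
# multiplier averaged over the population.
gene_factors <- function(state, config, annotation) {
  copy <- rep(1, nrow(annotation))
  cis <- rep(1, nrow(annotation))
  cnv <- config$cnv_locus
  in_cnv <- annotation$chrom == cnv$chrom &
    annotation$start <= cnv$end & annotation$end >= cnv$start
  if (any(in_cnv) && cnv$copies > 1) {
    idx <- site_nearest(state$map, cnv$chrom, (cnv$start + cnv$end) / 2)
    copy[in_cnv] <- mean_copy_ratio(state, idx, cnv$copies)
  }
  eq <- config$cis_eqtl
  if (!is.null(eq) && nrow(eq)) {
    for (i in seq_len(nrow(eq))) {
      hit <- annotation$chrom == eq$chrom[i] &
        annotation$start <= eq$pos[i] & annotation$end >= eq$pos[i]
      if (any(hit)) {
        idx <- site_nearest(state$map, eq$chrom[i], eq$pos[i])
        cis[hit] <- cis[hit] * mean_cis_factor(state, idx, eq$multiplier[i])
      }
    }
  }
  list(copy = copy, cis = cis, cnv_genes = annotation$gene_id[in_cnv])
}

#' Emit efficiency-model qPCR threshold cycles
#'
#' Ct values follow `Ct = Ct0 - log_E(copies) + Normal(0, sd)` for the
#' target amplicon and `Ct = Ct0 + Normal(0, sd)` for the single-copy
#' reference amplicon, in the configured number of technical replicates.
#'
#' @param copy_number Named numeric vector of true target copy numbers per
#'   sample (all positive).
#' @param config A [sim_config()] (supplies efficiencies, intercept, noise).
#' @param n_replicates Technical replicates per sample and amplicon
#'   (default 2, i.e. duplicates).
#' @return data.frame `sample`, `amplicon`, `replicate`, `ct` with the
#'   amplification efficiencies attached as the `"efficiency"` attribute.
#' @export
emit_qpcr <- function(copy_number, config, n_replicates = 2L) {
  if (any(copy_number <= 0)) stop("copy numbers must be positive")
  if (is.null(names(copy_number))) stop("copy_number must be named by sample")
  q <- config$qpcr
  grid <- expand.grid(replicate = seq_len(n_replicates),
                      sample = names(copy_number),
                      amplicon = c("target", "reference"),
                      stringsAsFactors = FALSE)
  mu <- ifelse(grid$amplicon == "target",
               q$ct0 - log(copy_number[grid$sample]) / log(q$E_target),
               q$ct0)
  grid$ct <- mu + rnorm(nrow(grid), 0, q$sd)
  out <- grid[, c("sample", "amplicon", "replicate", "ct")]
  attr(out, "efficiency") <- c(target = q$E_target, reference = q$E_reference)
  out
}

#' Emit dose-response mortality for a mixture of genotype classes
#'
#' Deaths at each dose are binomial with success probability equal to the
#' mixture of per-class probit mortality curves,
#' `p(d) = sum_k prop_k * Phi(slope_k * (log10 d - log10 LC50_k))`.
#'
#' @param genotype_mix data.frame with `genotype` and `proportion`
#'   (proportions summing to 1; genotypes present in
#'   `config$dose_response`).
#' @param config A [sim_config()].
#' @param doses Positive concentrations (mg/L).
#' @param n_per_dose Individuals exposed per dose.
#' @param population Label written in the output table.
#' @return data.frame `population`, `dose`, `n`, `dead`.
#' @export
emit_dose_response <- function(genotype_mix, config, doses, n_per_dose,
                               population = "pop") {
  if (any(doses <= 0)) stop("doses must be positive")
  if (abs(sum(genotype_mix$proportion) - 1) > 1e-8) {
    stop("genotype proportions must sum to 1")
  }
  dr <- config$dose_response
  miss <- setdiff(genotype_mix$genotype, dr$genotype)
  if (length(miss)) stop("unknown genotype class: ", paste(miss, collapse = ", "))
  p <- vapply(doses, function(d) {
    sum(vapply(seq_len(nrow(genotype_mix)), function(i) {
      row <- dr[dr$genotype == genotype_mix$genotype[i], ]
      genotype_mix$proportion[i] *
        pnorm(row$slope * (log10(d) - row$log10_lc50))
    }, numeric(1)))
  }, numeric(1))
  data.frame(population = population, dose = doses, n = n_per_dose,
             dead = rbinom(length(doses), n_per_dose, p))
}

#' Emit the full set of inheritance bioassay tables
#'
#' Generates mortality tables for the susceptible and resistant parent
#' strains, the two reciprocal F1s, and a backcross that is a 50:50 mixture
#' of F1-like and resistant-like genotypes (the expectation under a single
#' recessive resistance locus in a haplodiploid backcross).
#'
#' @param config A [sim_config()].
#' @param doses Concentrations assayed.
#' @param n_per_dose Individuals per dose.
#' @return Named list of mortality data.frames: `S`, `R`, `F1a`, `F1b`, `BC`.
#' @export
emit_inheritance_assays <- function(config,
                                    doses = c(2, 5, 10, 20, 50, 100, 200,
                                              500, 1000, 2000),
                                    n_per_dose = 120L) {
  withr::with_seed(substream_seed(config$seed, "dose"), {
    pure <- function(g) data.frame(genotype = g, proportion = 1)
    list(
      S = emit_dose_response(pure("S"), config, doses, n_per_dose, "S"),
      R = emit_dose_response(pure("R"), config, doses, n_per_dose, "R"),
      F1a = emit_dose_response(pure("F1"), config, doses, n_per_dose, "F1a"),
      F1b = emit_dose_response(pure("F1"), config, doses, n_per_dose, "F1b"),
      BC = emit_dose_response(
        data.frame(genotype = c("F1", "R"), proportion = c(0.5, 0.5)),
        config, doses, n_per_dose, "BC")
    )
  })
}

#' Simulate the complete experiment and emit every pipeline input
#'
#' Runs the founding cross, propagates the paired selected/control
#' populations, and emits pooled DNA site counts, exonic RNA site counts,
#' per-gene DNA coverage and RNA count matrices (with CNV and cis-eQTL
#' dosage effects), a qPCR Ct table, a differential-expression summary
#' table derived from the true dosage effects, and the inheritance
#' bioassays — all with the ground truth attached.
#'
#' @param config A [sim_config()].
#' @param keep_states Keep the final `population_state`s (memory-heavy;
#'   default FALSE).
#' @return An object of class `bsa_simulation`.
#' @export
simulate_experiment <- function(config, keep_states = FALSE) {
  founders <- make_founders(config)
  annotation <- gene_annotation(config)
  n_sites <- nrow(founders$sites)
  n_genes <- nrow(annotation)
  samples <- c(paste0("R", seq_len(config$n_pairs)),
               paste0("S", seq_len(config$n_pairs)))
  ref <- alt <- matrix(0L, n_sites, 2L * config$n_pairs,
                       dimnames = list(NULL, samples))
  exonic <- exonic_site_rows(founders, annotation)
  rna_ref <- rna_alt <- matrix(0L, length(exonic), 2L * config$n_pairs,
                               dimnames = list(NULL, samples))
  dna_genes <- rna_genes <- matrix(0L, n_genes, 2L * config$n_pairs,
                                   dimnames = list(annotation$gene_id, samples))
  causal_freq <- matrix(NA_real_, nrow(config$causal_loci),
                        2L * config$n_pairs, dimnames = list(NULL, samples))
  copies_true <- setNames(numeric(2L * config$n_pairs), samples)
  states <- if (keep_states) list() else NULL

  pool_seed <- substream_seed(config$seed, "pool")
  for (pr in seq_len(config$n_pairs)) {
    pair <- run_pair(founders, config, pr)
    for (tr in c("selected", "control")) {
      st <- pair[[tr]]
      smp <- paste0(if (tr == "selected") "R" else "S", pr)
      withr::with_seed(pool_seed + 7L * pr + (tr == "selected"), {
        pfreq <- pooled_site_freq(st, founders, config)
        dna <- emit_pool_reads(st, founders, config, freq = pfreq)
        rna <- emit_pool_reads(st, founders, config,
                               depth_mean = config$rna_site_depth_mean,
                               freq = pfreq)
        gf <- gene_factors(st, config, annotation)
        dna_g <- rpois(n_genes, config$dna_depth_mean * gf$copy)
        rna_g <- rnbinom(n_genes, size = 1 / config$nb_dispersion,
                         mu = config$rna_depth_mean * gf$copy * gf$cis)
      })
      ref[, smp] <- dna$ref
      alt[, smp] <- dna$alt
      rna_ref[, smp] <- rna$ref[exonic]
      rna_alt[, smp] <- rna$alt[exonic]
      dna_genes[, smp] <- dna_g
      rna_genes[, smp] <- rna_g
      if (length(founders$map$causal_idx)) {
        causal_freq[, smp] <- female_allele_freq(st)[founders$map$causal_idx]
      }
      cnv <- config$cnv_locus
      copies_true[smp] <- mean_copy_ratio(
        st, site_nearest(st$map, cnv$chrom, (cnv$start + cnv$end) / 2),
        cnv$copies)
      if (keep_states) states[[smp]] <- st
    }
  }

  site_cols <- c("chrom", "pos")
  withr::with_seed(substream_seed(config$seed, "qpcr"), {
    qpcr <- emit_qpcr(c(copies_true, calibrator = 1), config)
  })
  cnv_genes <- gene_factors_template(config, annotation)
  de_table <- withr::with_seed(substream_seed(config$seed, "de"), {
    emit_de_table(dna_genes, rna_genes, annotation, config, samples)
  })

  structure(list(
    config = config,
    founders = founders,
    annotation = annotation,
    samples = samples,
    pairs = data.frame(pair = seq_len(config$n_pairs),
                       selected = paste0("R", seq_len(config$n_pairs)),
                       control = paste0("S", seq_len(config$n_pairs))),
    dna_sites = pool_counts(founders$sites[, site_cols], ref, alt),
    rna_sites = pool_counts(founders$sites[exonic, site_cols], rna_ref, rna_alt),
    dna_gene_counts = dna_genes,
    rna_gene_counts = rna_genes,
    qpcr = qpcr,
    de_table = de_table,
    states = states,
    truth = list(causal_loci = config$causal_loci,
                 causal_freq = causal_freq,
                 cnv_locus = config$cnv_locus,
                 cnv_genes = cnv_genes,
                 copies_true = copies_true,
                 sites = founders$sites)
  ), class = "bsa_simulation")
}

#' @export
print.bsa_simulation <- function(x, ...) {
  cat(sprintf("<bsa_simulation> %d pairs, %d sites (%d informative), %d genes\n",
              x$config$n_pairs, nrow(x$founders$sites),
              sum(x$founders$sites$informative), nrow(x$annotation)))
  invisible(x)
}

# Rows of the full site table that fall inside gene models ("exonic").
exonic_site_rows <- function(founders, annotation) {
  keep <- rep(FALSE, nrow(founders$sites))
  for (ci in unique(annotation$chrom)) {
    on_chr <- which(founders$sites$chrom == ci)
    ann <- annotation[annotation$chrom == ci, ]
    # genes tile at a constant spacing, so membership is positional
    pos <- founders$sites$pos[on_chr]
    gi <- findInterval(pos, ann$start)
    inside <- gi >= 1 & pos <= ann$end[pmax(gi, 1L)]
    keep[on_chr[inside]] <- TRUE
  }
  which(keep)
}

gene_factors_template <- function(config, annotation) {
  cnv <- config$cnv_locus
  annotation$gene_id[annotation$chrom == cnv$chrom &
                       annotation$start <= cnv$end &
                       annotation$end >= cnv$start]
}

# Differential-expression summary derived from the simulation's own dosage
# ground truth: fold change of selected over control normalized means, a
# small adjusted p for genes with strong true effects, uniform otherwise.
# The pipeline consumes such a table; it never infers one.
emit_de_table <- function(dna_genes, rna_genes, annotation, config, samples) {
  sel <- grepl("^R", samples)
  sf <- size_factors(rna_genes)
  norm <- sweep(rna_genes, 2, sf, "/")
  mean_sel <- rowMeans(norm[, sel, drop = FALSE])
  mean_ctl <- rowMeans(norm[, !sel, drop = FALSE])
  ratio <- ifelse(mean_ctl > 0, mean_sel / mean_ctl, NA_real_)
  fc <- ifelse(!is.na(ratio) & ratio < 1 & ratio > 0, -1 / ratio, ratio)
  strong <- !is.na(fc) & abs(fc) >= 2
  padj <- ifelse(strong, 1e-6, runif(length(fc), 0.05, 1))
  data.frame(gene_id = annotation$gene_id, fc = fc, padj = padj)
}
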