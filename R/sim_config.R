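#' Simulation configuration for the haplodiploid cross and selection experiment
#'
#' Bundles every parameter of the forward simulator: the toy genome, the
#' cross design (an inbred homozygous mother strain crossed to a single
#' haploid male drawn from a heterozygous resistant strain), the paired
#' selected/control propagation, and the sequencing, qPCR and dose-response
#' emission models.  The defaults emulate the study design this package is
#' built around: 11 paired populations of ~650 females propagated for ~35
#' generations, pooled DNA from up to 1,000 females, three strongly selected
#' loci, and a copy-number-variable block of five consecutive genes carried
#' at three copies by the resistant parent.
#'
#' @param chromosome_lengths Integer vector of chromosome lengths in bp,
#'   ordered by decreasing length.  Default `c(7.5e6, 5e6, 2.5e6)`.
#' @param snp_density Informative-site density, sites per kb (default 2).
#' @param strain_het_prop Proportion of polymorphic sites at which the
#'   resistant strain is heterozygous (the remainder are homozygous for the
#'   non-maternal allele).  Default 0.6.
#' @param n_pairs Number of paired selected/control populations (default 11).
#' @param n_females Census number of females per population (default 650).
#' @param pool_size Number of females pooled for DNA sequencing (default
#'   1000; capped at the census size).
#' @param n_generations Number of generations of propagation (default 35).
#' @param causal_loci data.frame with columns `chrom`, `pos`, `s`, `h`:
#'   position of each selected locus, its selection coefficient `s` and
#'   dominance `h` of the resistant allele in females.  Default: three loci
#'   (two on chromosome 1, one on chromosome 2) with s = 0.8 and h = 0.1
#'   (incompletely recessive resistance).
#' @param cnv_locus List with `chrom`, `start`, `end`, `copies`: a genomic
#'   block carried at `copies` copies per haploid genome by the resistant
#'   parent and one copy by the mother strain.  The default spans five
#'   consecutive genes (~14 kb) around the chromosome-2 causal locus at
#'   three copies.
#' @param cnv_cost Viability cost per resistant haplotype at the CNV locus,
#'   applied only in the unselected (control) treatment (default 0.1):
#'   without pesticide exposure the amplified haplotype is purged, so
#'   control populations converge to single copy while the benefit under
#'   selection dominates in the selected treatment.
#' @param gene_length,gene_spacing Gene model geometry in bp used by the
#'   built-in annotation generator (genes tile each chromosome at regular
#'   offsets).
#' @param dna_depth_mean Mean pooled DNA read depth per site and mean
#'   per-gene DNA coverage (default 100).
#' @param rna_depth_mean Mean per-gene RNA expected count at baseline
#'   (default 200).
#' @param rna_site_depth_mean Mean RNA read depth at exonic informative
#'   sites for the RNA-based BSA scan (default 40).
#' @param nb_dispersion Negative-binomial dispersion of RNA counts
#'   (default 0.05).
#' @param cis_eqtl data.frame with columns `chrom`, `pos`, `multiplier`:
#'   genes overlapping `pos` have expression multiplied by
#'   `multiplier^dose`, where dose is the number of resistant haplotypes an
#'   individual carries locally.  Defaults place a strong cis-eQTL at the
#'   first causal locus and a weak one at the second.
#' @param qpcr List with per-amplicon amplification efficiencies
#'   `E_target`, `E_reference` in (1, 2], intercept `ct0`, and replicate
#'   noise `sd` (cycles).
#' @param dose_response data.frame with columns `genotype`, `slope`,
#'   `log10_lc50`: probit slope (on log10 dose) and log10 LC50 per genotype
#'   class.  Defaults give a susceptible strain (LC50 ~5 mg/L), a resistant
#'   strain (LC50 ~1600 mg/L) and an F1 with incompletely recessive
#'   resistance.
#' @param seed Integer seed; a fixed seed makes every emitted table
#'   byte-identical across runs.
#'
#' @return An object of class `sim_config` (a validated list).
#' @export
sim_config <- function(chromosome_lengths = c(7.5e6, 5e6, 2.5e6),
                       snp_density = 2,
                       strain_het_prop = 0.6,
                       n_pairs = 11L,
                       n_females = 650L,
                       pool_size = 1000L,
                       n_generations = 35L,
                       causal_loci = data.frame(
                         chrom = c(1L, 1L, 2L),
                         pos = c(2.0e6, 5.5e6, 2.4e6),
                         s = c(0.15, 0.15, 0.15),
                         h = c(0.1, 0.1, 0.1)
                       ),
                       cnv_locus = NULL,
                       cnv_cost = 0.1,
                       gene_length = 2000L,
                       gene_spacing = 3000L,
                       dna_depth_mean = 100,
                       rna_depth_mean = 200,
                       rna_site_depth_mean = 40,
                       nb_dispersion = 0.05,
                       cis_eqtl = data.frame(
                         chrom = c(1L, 1L),
                         pos = c(2.0e6, 5.5e6),
                         multiplier = c(2.25, 1.4)
                       ),
                       qpcr = list(E_target = 1.9, E_reference = 1.95,
                                   ct0 = 32, sd = 0.15),
                       dose_response = data.frame(
                         genotype = c("S", "F1", "R"),
                         slope = c(2.2, 2.0, 2.0),
                         log10_lc50 = c(0.7, 1.2, 3.2)
                       ),
                       seed = 1L) {
  chromosome_lengths <- as.numeric(chromosome_lengths)
  if (any(chromosome_lengths <= 0)) stop("chromosome lengths must be positive")
  if (is.unsorted(rev(chromosome_lengths))) {
    stop("chromosomes must be ordered by decreasing length")
  }
  if (snp_density <= 0) stop("snp_density must be positive")
  if (strain_het_prop <= 0 || strain_het_prop > 1) {
    stop("strain_het_prop must be in (0, 1]")
  }
  stopifnot(n_pairs >= 1, n_females >= 2, pool_size >= 1, n_generations >= 1)
  if (nrow(causal_loci)) {
    stopifnot(all(causal_loci$s >= 0), all(causal_loci$s <= 1),
              all(causal_loci$h >= 0), all(causal_loci$h <= 1),
              all(causal_loci$chrom >= 1),
              all(causal_loci$chrom <= length(chromosome_lengths)),
              all(causal_loci$pos >= 1),
              all(causal_loci$pos <= chromosome_lengths[causal_loci$chrom]))
  }
  if (is.null(cnv_locus)) {
    # Align the default CNV block to the gene grid on chromosome 2 so that
    # it spans exactly five consecutive genes near the third causal locus.
    g0 <- floor(2.4e6 / gene_spacing) * gene_spacing + 1
    cnv_locus <- list(chrom = 2L, start = g0,
                      end = g0 + 4L * gene_spacing + gene_length - 1L,
                      copies = 3L)
  }
  stopifnot(cnv_locus$copies >= 1, cnv_locus$start >= 1,
            cnv_locus$end > cnv_locus$start,
            cnv_locus$chrom >= 1,
            cnv_locus$chrom <= length(chromosome_lengths),
            cnv_locus$end <= chromosome_lengths[cnv_locus$chrom])
  stopifnot(cnv_cost >= 0, cnv_cost < 1)
  if (dna_depth_mean <= 0 || rna_depth_mean <= 0 || rna_site_depth_mean <= 0) {
    stop("sequencing depth means must be positive")
  }
  if (nb_dispersion <= 0) stop("nb_dispersion must be positive")
  if (qpcr$E_target <= 1 || qpcr$E_target > 2 ||
      qpcr$E_reference <= 1 || qpcr$E_reference > 2) {
    stop("qPCR efficiencies must lie in (1, 2]")
  }
  if (qpcr$sd < 0) stop("qPCR replicate noise sd must be non-negative")
  stopifnot(all(dose_response$slope > 0))
  cfg <- list(
    chromosome_lengths = chromosome_lengths,
    snp_density = snp_density,
    strain_het_prop = strain_het_prop,
    n_pairs = as.integer(n_pairs),
    n_females = as.integer(n_females),
    pool_size = as.integer(pool_size),
    n_generations = as.integer(n_generations),
    causal_loci = causal_loci,
    cnv_locus = cnv_locus,
    cnv_cost = cnv_cost,
    gene_length = as.integer(gene_length),
    gene_spacing = as.integer(gene_spacing),
    dna_depth_mean = dna_depth_mean,
    rna_depth_mean = rna_depth_mean,
    rna_site_depth_mean = rna_site_depth_mean,
    nb_dispersion = nb_dispersion,
    cis_eqtl = cis_eqtl,
    qpcr = qpcr,
    dose_response = dose_response,
    seed = as.integer(seed)
  )
  structure(cfg, class = "sim_config")
}

#' @export
print.sim_config <- function(x, ...) {
  cat("<sim_config>\n")
  cat(sprintf("  genome: %d chromosomes, %.1f Mb total, %.1f sites/kb\n",
              length(x$chromosome_lengths),
              sum(x$chromosome_lengths) / 1e6, x$snp_density))
  cat(sprintf("  design: %d pairs x %d females x %d generations\n",
              x$n_pairs, x$n_females, x$n_generations))
  cat(sprintf("  causal loci: %d; CNV block chr%d:%d-%d (%d copies)\n",
              nrow(x$causal_loci), x$cnv_locus$chrom, x$cnv_locus$start,
              x$cnv_locus$end, x$cnv_locus$copies))
  invisible(x)
}

#' Genome layout of ordered chromosomes
#'
#' @param chrom Chromosome identifiers (coerced to character).
#' @param length Chromosome lengths in bp, ordered by decreasing length.
#' @return A `genome_layout` data.frame with columns `chrom` and `length`.
#' @export
genome_layout <- function(chrom, length) {
  length <- as.numeric(length)
  if (any(length <= 0)) stop("chromosome lengths must be positive")
  if (is.unsorted(rev(length))) {
    stop("chromosomes must be ordered by decreasing length")
  }
  structure(data.frame(chrom = as.character(chrom), length = length,
                       stringsAsFactors = FALSE),
            class = c("genome_layout", "data.frame"))
}

#' @rdname genome_layout
#' @param config A [sim_config()].
#' @export
layout_from_config <- function(config) {
  genome_layout(seq_along(config$chromosome_lengths),
                config$chromosome_lengths)
}
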