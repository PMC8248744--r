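#' Draw the founder genomes of the mapping cross
#'
#' Emulates the founding cross: diploid females of an inbred, fully
#' homozygous mother strain are crossed to a single haploid male drawn at
#' random from a heterozygous resistant strain.  Polymorphic sites are
#' placed uniformly along each chromosome at the configured density; the
#' mother is homozygous for the reference allele everywhere, the resistant
#' strain is heterozygous at a configurable proportion of sites and
#' homozygous for the alternate allele at the rest.  A site is informative
#' when the allele the male transmitted differs from the maternal allele;
#' the table of informative sites with the ground-truth transmitted allele
#' is the oracle used by the site-inference tests.
#'
#' @param config A [sim_config()].
#' @return An object of class `founder_genomes`: a list with `sites` (the
#'   full site table: `chrom`, `pos`, `mother_allele`, `strain_genotype`,
#'   `male_allele`, `informative`), the informative-site `map` used by the
#'   population simulator, and the causal-locus site indices.
#' @export
make_founders <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  withr::with_seed(substream_seed(config$seed, "founders"), {
    per_chrom <- lapply(seq_along(config$chromosome_lengths), function(ci) {
      len <- config$chromosome_lengths[ci]
      n <- max(1L, round(len / 1000 * config$snp_density))
      pos <- sort(sample.int(len, n))
      data.frame(chrom = ci, pos = pos)
    })
    sites <- do.call(rbind, per_chrom)
    n <- nrow(sites)
    sites$mother_allele <- 0L
    het <- runif(n) < config$strain_het_prop
    sites$strain_genotype <- ifelse(het, "0/1", "1/1")
    # The single haploid male is one random gamete of the strain: at
    # heterozygous sites he carries either allele with probability 1/2.
    sites$male_allele <- ifelse(het, as.integer(runif(n) < 0.5), 1L)
    sites$informative <- sites$male_allele != sites$mother_allele
  })
  if (!any(sites$informative)) stop("degenerate founders: zero informative sites")
  founders <- list(
    sites = sites,
    map = informative_map(sites, config),
    config_seed = config$seed
  )
  class(founders) <- "founder_genomes"
  founders
}

# Index structure over informative sites: positions per chromosome, 0-based
# row offsets for the C++ meiosis kernel, and causal/CNV site lookups.
informative_map <- function(sites, config) {
  inf <- sites[sites$informative, , drop = FALSE]
  chroms <- seq_along(config$chromosome_lengths)
  nsites <- vapply(chroms, function(ci) sum(inf$chrom == ci), integer(1))
  offset <- cumsum(c(0L, nsites[-length(nsites)]))
  causal <- config$causal_loci
  causal_idx <- integer(0)
  if (nrow(causal)) {
    causal_idx <- vapply(seq_len(nrow(causal)), function(i) {
      on_chr <- which(inf$chrom == causal$chrom[i])
      if (!length(on_chr)) stop("no informative site on causal chromosome")
      on_chr[which.min(abs(inf$pos[on_chr] - causal$pos[i]))]
    }, integer(1))
  }
  cnv <- config$cnv_locus
  cnv_idx <- integer(0)
  if (config$cnv_cost > 0 && cnv$copies > 1 &&
        any(inf$chrom == cnv$chrom)) {
    on_chr <- which(inf$chrom == cnv$chrom)
    cnv_idx <- on_chr[which.min(abs(inf$pos[on_chr] -
                                      (cnv$start + cnv$end) / 2))]
  }
  list(
    chrom = inf$chrom,
    pos = inf$pos,
    site_row = which(sites$informative),
    chrom_offset = as.integer(offset),
    chrom_nsites = as.integer(nsites),
    chrom_lengths = config$chromosome_lengths,
    causal_idx = causal_idx,
    causal_s = causal$s %||% numeric(0),
    causal_h = causal$h %||% numeric(0),
    cnv_idx = cnv_idx,
    cnv_cost = config$cnv_cost
  )
}

# Per-treatment viability tables: one column per locus under selection.
# Selected treatment: the resistant allele is favored at every causal locus
# (females 1-s / 1-s(1-h) / 1 by dose, haploid males 1-s / 1).  Control
# treatment: the amplified CNV haplotype pays a per-copy cost
# (females (1-c)^dose, males 1 / 1-c).
fitness_tables <- function(map, treatment) {
  if (treatment == "selected" && length(map$causal_idx)) {
    s <- map$causal_s
    h <- map$causal_h
    list(idx = as.integer(map$causal_idx) - 1L,
         female = rbind(1 - s, 1 - s * (1 - h), rep(1, length(s))),
         male = rbind(1 - s, rep(1, length(s))))
  } else if (treatment == "control" && length(map$cnv_idx)) {
    c0 <- map$cnv_cost
    list(idx = as.integer(map$cnv_idx) - 1L,
         female = cbind(c(1, 1 - c0, (1 - c0)^2)),
         male = cbind(c(1, 1 - c0)))
  } else {
    list(idx = integer(0),
         female = matrix(numeric(0), 3, 0),
         male = matrix(numeric(0), 2, 0))
  }
}

#' Initialize a population of F1 females and their first sons
#'
#' Generation 0 consists of `n_females` F1 females, all heterozygous at
#' every informative site (maternal haplotype from the inbred mother,
#' paternal haplotype from the single haploid sire), plus an equal number
#' of haploid males drawn as recombinant gametes of those females.
#'
#' @param founders A [make_founders()] result.
#' @param config A [sim_config()].
#' @param treatment `"selected"` or `"control"`.
#' @return An object of class `population_state`.
#' @export
init_population <- function(founders, config, treatment = c("control", "selected")) {
  treatment <- match.arg(treatment)
  n_inf <- length(founders$map$pos)
  n_f <- config$n_females
  h1 <- matrix(as.raw(0), n_inf, n_f)  # maternal haplotype: all reference
  h2 <- matrix(as.raw(1), n_inf, n_f)  # paternal haplotype: all transmitted
  state <- structure(list(
    female_h1 = h1, female_h2 = h2,
    male_h = NULL, generation = 0L, treatment = treatment,
    map = founders$map
  ), class = "population_state")
  state$male_h <- draw_gametes(state, config$n_females)
  state
}

#' @export
print.population_state <- function(x, ...) {
  cat(sprintf("<population_state> generation %d (%s): %d females, %d males, %d sites\n",
              x$generation, x$treatment, ncol(x$female_h1), ncol(x$male_h),
              nrow(x$female_h1)))
  invisible(x)
}

# One recombinant gamete per requested offspring, mothers sampled uniformly.
# Exactly one crossover per chromosome at a uniform bp position.
draw_gametes <- function(state, n_gametes, mothers = NULL) {
  map <- state$map
  if (is.null(mothers)) {
    mothers <- sample.int(ncol(state$female_h1), n_gametes, replace = TRUE)
  }
  .meiosis_gametes(state$female_h1, state$female_h2, as.integer(mothers),
                   as.integer(map$pos), map$chrom_offset, map$chrom_nsites,
                   as.numeric(map$chrom_lengths))
}

#' Advance a population by one generation
#'
#' Implements the haplodiploid (arrhenotokous) life cycle: daughters unite a
#' recombinant maternal gamete with the haplotype of a random male; sons
#' develop from an unfertilized recombinant maternal gamete.  In the
#' selected treatment, viability selection acts on each offspring with
#' fitness multiplicative over causal loci — females: `1 - s` with zero
#' resistant alleles, `1 - s(1-h)` with one, `1` with two; haploid males:
#' `1 - s` (susceptible allele) or `1` (resistant).  In the control
#' treatment the amplified CNV haplotype pays the configured per-copy
#' viability cost, emulating purging of the amplification in the absence of
#' pesticide exposure.  Survivors refill the census.
#'
#' @param state A `population_state`.
#' @param config A [sim_config()].
#' @return The next `population_state`.
#' @export
advance_generation <- function(state, config) {
  stopifnot(inherits(state, "population_state"))
  if (ncol(state$female_h1) == 0 || ncol(state$male_h) == 0) {
    stop("empty population at generation ", state$generation)
  }
  map <- state$map
  fit <- fitness_tables(map, state$treatment)
  nxt <- tryCatch(
    .advance_pop(state$female_h1, state$female_h2, state$male_h,
                 as.integer(map$pos), map$chrom_offset, map$chrom_nsites,
                 as.numeric(map$chrom_lengths),
                 fit$idx, fit$female, fit$male,
                 config$n_females, config$n_females),
    error = function(e) {
      stop("generation ", state$generation + 1L, ": ", conditionMessage(e))
    })
  state$female_h1 <- nxt$female_h1
  state$female_h2 <- nxt$female_h2
  state$male_h <- nxt$male_h
  state$generation <- state$generation + 1L
  state
}

#' Propagate one paired selected/control experiment
#'
#' A shared generation-0 population is split into a selected and a control
#' sister population, each propagated for `n_generations` generations.
#'
#' @param founders A [make_founders()] result.
#' @param config A [sim_config()].
#' @param pair Integer pair index (seeds the pair's private random stream).
#' @return List with `selected` and `control` final `population_state`s.
#' @export
run_pair <- function(founders, config, pair = 1L) {
  seed <- substream_seed(config$seed, "population") + 1000L * as.integer(pair)
  withr::with_seed(seed, {
    base <- init_population(founders, config, "control")
    selected <- base
    selected$treatment <- "selected"
    control <- base
    for (g in seq_len(config$n_generations)) {
      selected <- advance_generation(selected, config)
      control <- advance_generation(control, config)
    }
    list(selected = selected, control = control)
  })
}

#' Frequency of the transmitted (resistant-parent) allele among females
#'
#' @param state A `population_state`.
#' @return Numeric vector over informative sites.
#' @export
female_allele_freq <- function(state) {
  (rowSums(state$female_h1 != as.raw(0)) +
     rowSums(state$female_h2 != as.raw(0))) /
    (2 * ncol(state$female_h1))
}
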