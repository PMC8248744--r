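#' Site filtering parameters
#'
#' @param nonseg_threshold Frequency at or above which an allele shared by
#'   both members of a pair marks the site as non-segregating for that pair
#'   (default 0.95; the comparison is `>=`, so exactly 0.95 is dropped).
#' @param min_pool_freq_for_inference Minimum frequency of the non-maternal
#'   allele in at least one offspring pool for it to be called the
#'   transmitted allele at a strain-heterozygous site (default 0.05; guards
#'   transmission inference against sequencing-error alleles).
#' @return A `site_filter_params` list.
#' @export
site_filter_params <- function(nonseg_threshold = 0.95,
                               min_pool_freq_for_inference = 0.05) {
  if (nonseg_threshold <= 0.5 || nonseg_threshold > 1) {
    stop("nonseg_threshold must be in (0.5, 1]")
  }
  structure(list(nonseg_threshold = nonseg_threshold,
                 min_pool_freq_for_inference = min_pool_freq_for_inference),
            class = "site_filter_params")
}

#' Infer the transmitted paternal allele at every site
#'
#' In a haplodiploid cross of an inbred homozygous mother to a single
#' haploid sire, the sire contributed exactly one allele per site.  At
#' sites where the sire's source strain is homozygous that allele is known;
#' at its heterozygous sites the transmitted allele is inferred from the
#' offspring pools: the non-maternal allele is called transmitted when its
#' frequency exceeds `min_pool_freq_for_inference` in at least one pool,
#' otherwise the maternal allele was transmitted and the site is
#' non-informative.  A site is informative exactly when the transmitted
#' allele differs from the maternal allele.  Sites with a heterozygous
#' mother genotype are flagged `low_quality` and never used.
#'
#' @param parents data.frame with `chrom`, `pos`, `mother_gt`, `strain_gt`
#'   (diploid genotypes as `"0/0"`, `"0/1"`, `"1/1"`).
#' @param pools A `pool_counts` object of per-population ref/alt read
#'   counts at the same sites (matched on `chrom` and `pos`).
#' @param params A [site_filter_params()].
#' @return A `site_records` object: the per-site table (`transmitted_allele`
#'   0/1, `informative`, `excluded_reason`) plus matrices `freq`
#'   (transmitted-allele frequency) and `depth` per population.
#' @export
assign_transmitted_alleles <- function(parents, pools,
                                       params = site_filter_params()) {
  key_p <- paste(parents$chrom, parents$pos)
  key_c <- paste(pools$sites$chrom, pools$sites$pos)
  m <- match(key_p, key_c)
  if (anyNA(m)) stop("parent sites missing from pool counts")
  ref <- pools$ref[m, , drop = FALSE]
  alt <- pools$alt[m, , drop = FALSE]
  depth <- ref + alt
  alt_freq <- ifelse(depth > 0, alt / depth, NA_real_)

  split_gt <- function(gt) {
    a <- strsplit(gt, "[/|]")
    bad <- lengths(a) != 2
    if (any(bad)) stop("malformed genotype at row ", which(bad)[1])
    list(a1 = as.integer(vapply(a, `[`, "", 1)),
         a2 = as.integer(vapply(a, `[`, "", 2)))
  }
  mo <- split_gt(parents$mother_gt)
  st <- split_gt(parents$strain_gt)
  mother_het <- mo$a1 != mo$a2
  maternal <- mo$a1
  nonmat <- 1L - maternal
  strain_het <- st$a1 != st$a2
  strain_allele <- st$a1  # strain's allele when homozygous

  # frequency of the non-maternal allele per pool
  nonmat_freq <- ifelse(rep(nonmat, ncol(alt_freq)) == 1L, alt_freq, 1 - alt_freq)
  dim(nonmat_freq) <- dim(alt_freq)
  seen <- rowSums(nonmat_freq > params$min_pool_freq_for_inference,
                  na.rm = TRUE) > 0

  transmitted <- ifelse(strain_het,
                        ifelse(seen, nonmat, maternal),
                        strain_allele)
  informative <- !mother_het & transmitted != maternal
  reason <- ifelse(mother_het, "low_quality", "none")
  transmitted[mother_het] <- NA_integer_

  tfreq <- ifelse(rep(transmitted, ncol(alt_freq)) == 1L, alt_freq, 1 - alt_freq)
  dim(tfreq) <- dim(alt_freq)
  colnames(tfreq) <- colnames(depth) <- pools$samples

  structure(list(
    sites = data.frame(chrom = parents$chrom, pos = parents$pos,
                       transmitted_allele = transmitted,
                       informative = informative,
                       excluded_reason = reason),
    freq = tfreq, depth = depth, samples = pools$samples,
    params = params
  ), class = "site_records")
}

#' @export
print.site_records <- function(x, ...) {
  cat(sprintf("<site_records> %d sites (%d informative, %d excluded), %d samples\n",
              nrow(x$sites), sum(x$sites$informative, na.rm = TRUE),
              sum(x$sites$excluded_reason != "none"), length(x$samples)))
  invisible(x)
}

#' Drop non-segregating sites per pair
#'
#' For each paired selected/control population, a site is dropped when the
#' same allele is at frequency `>= nonseg_threshold` in both members
#' (either allele near fixation in both drops the site for that pair).  A
#' site is excluded globally, with reason `nonsegregating`, only when it is
#' dropped for every pair; otherwise the per-pair usability is recorded in
#' the `pair_keep` matrix.
#'
#' @param records A `site_records` object.
#' @param pairs data.frame with columns `pair`, `selected`, `control`
#'   naming the paired samples.
#' @param params A [site_filter_params()].
#' @return The `site_records` object with `pair_keep` (sites x pairs
#'   logical matrix) and updated `excluded_reason`.
#' @export
filter_nonsegregating <- function(records, pairs,
                                  params = records$params %||% site_filter_params()) {
  stopifnot(inherits(records, "site_records"))
  miss <- setdiff(c(pairs$selected, pairs$control), records$samples)
  if (length(miss)) {
    stop("pair member(s) missing from records: ", paste(miss, collapse = ", "))
  }
  t <- params$nonseg_threshold
  keep <- matrix(TRUE, nrow(records$sites), nrow(pairs))
  colnames(keep) <- as.character(pairs$pair)
  for (i in seq_len(nrow(pairs))) {
    fs <- records$freq[, pairs$selected[i]]
    fc <- records$freq[, pairs$control[i]]
    high_t <- fs >= t & fc >= t            # transmitted allele fixed in both
    high_o <- (1 - fs) >= t & (1 - fc) >= t  # other allele fixed in both
    drop <- (high_t | high_o) & !is.na(fs) & !is.na(fc)
    keep[drop, i] <- FALSE
  }
  all_dropped <- rowSums(keep) == 0
  records$sites$excluded_reason[all_dropped &
                                  records$sites$excluded_reason == "none"] <-
    "nonsegregating"
  records$pair_keep <- keep
  records
}

#' Usable sites for one pair
#'
#' Informative, non-excluded sites retained for the given pair, with the
#' transmitted-allele frequencies of both members.
#'
#' @param records A filtered `site_records` (after
#'   [filter_nonsegregating()]).
#' @param pair_row One row of the pairs table.
#' @return data.frame `chrom`, `pos`, `freq_selected`, `freq_control`.
#' @export
pair_sites <- function(records, pair_row) {
  keep <- records$sites$informative &
    records$sites$excluded_reason == "none"
  if (!is.null(records$pair_keep)) {
    keep <- keep & records$pair_keep[, as.character(pair_row$pair)]
  }
  keep[is.na(keep)] <- FALSE
  data.frame(chrom = records$sites$chrom[keep],
             pos = records$sites$pos[keep],
             freq_selected = records$freq[keep, pair_row$selected],
             freq_control = records$freq[keep, pair_row$control])
}
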