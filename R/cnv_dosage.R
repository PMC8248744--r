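#' Median-of-ratios size factors
#'
#' Per-sample scaling constants computed by the median-of-ratios method:
#' the reference is the per-gene geometric mean across samples (genes with
#' any zero count are excluded) and each sample's factor is the median over
#' genes of its count divided by the reference.
#'
#' @param matrix Non-negative genes-by-samples count matrix (DNA coverage
#'   or RNA counts).
#' @return Positive numeric vector of per-sample size factors.
#' @export
size_factors <- function(matrix) {
  if (ncol(matrix) < 2) stop("size factors need at least two samples")
  all_pos <- rowSums(matrix <= 0) == 0
  if (!any(all_pos)) stop("no gene with all-positive counts")
  m <- matrix[all_pos, , drop = FALSE]
  log_ref <- rowMeans(log(m))
  factors <- apply(m, 2, function(col) exp(median(log(col) - log_ref)))
  if (any(factors <= 0)) stop("non-positive size factor")
  factors
}

#' Per-gene coverage relative to a baseline sample group
#'
#' Counts are divided by their size factors and each gene's normalized
#' value is expressed relative to the mean normalized value over the
#' baseline (single-copy) samples.
#'
#' @param matrix Genes-by-samples count matrix.
#' @param factors Size factors from [size_factors()].
#' @param baseline_samples Column names (or indices) of the baseline group,
#'   typically the control/susceptible samples.
#' @return Genes-by-samples matrix of relative coverage (missing where the
#'   baseline mean is zero).
#' @export
relative_coverage <- function(matrix, factors, baseline_samples) {
  if (!length(baseline_samples)) stop("baseline is empty")
  norm <- sweep(matrix, 2, factors, "/")
  base <- rowMeans(norm[, baseline_samples, drop = FALSE])
  out <- sweep(norm, 1, base, "/")
  out[base == 0, ] <- NA_real_
  out
}

#' Call copy-number-gain segments from relative coverage
#'
#' Maximal runs of consecutive genes (in coordinate order) whose mean
#' relative coverage over the test samples reaches `gain_threshold` become
#' segments; the estimated copy number is the rounded mean relative
#' coverage over member genes (floored at 1).
#'
#' @param relative Per-gene relative coverage: either a named numeric
#'   vector (one value per gene) or a genes-by-samples matrix whose row
#'   means are used.
#' @param annotation Gene coordinates ordered by position (`gene_id`,
#'   `chrom`, `start`, `end`).
#' @param gain_threshold Minimum relative coverage for a gene to join a
#'   gain segment (default 1.5, separating one-copy from two-or-more-copy
#'   genes at moderate noise).
#' @return A `cnv_segments` data.frame: `chrom`, `start`, `end`, `copies`
#'   (integer), `copies_raw` (mean relative coverage), `n_genes`, and the
#'   member gene ids (comma-separated).
#' @export
call_cnv_segments <- function(relative, annotation, gain_threshold = 1.5) {
  if (is.matrix(relative)) relative <- rowMeans(relative, na.rm = TRUE)
  rel <- relative[annotation$gene_id]
  segs <- list()
  for (ci in unique(as.character(annotation$chrom))) {
    rows <- which(as.character(annotation$chrom) == ci)
    rows <- rows[order(annotation$start[rows])]
    gain <- which(!is.na(rel[rows]) & rel[rows] >= gain_threshold)
    if (!length(gain)) next
    run_id <- cumsum(c(1, diff(gain) != 1))
    for (r in split(gain, run_id)) {
      member <- rows[r]
      segs[[length(segs) + 1]] <- data.frame(
        chrom = ci,
        start = min(annotation$start[member]),
        end = max(annotation$end[member]),
        copies = max(1L, as.integer(round(mean(rel[member])))),
        copies_raw = mean(rel[member]),
        n_genes = length(member),
        genes = paste(annotation$gene_id[member], collapse = ",")
      )
    }
  }
  out <- if (length(segs)) do.call(rbind, segs) else
    data.frame(chrom = character(), start = numeric(), end = numeric(),
               copies = integer(), copies_raw = numeric(),
               n_genes = integer(), genes = character())
  class(out) <- c("cnv_segments", "data.frame")
  out
}

#' Efficiency-corrected qPCR copy number
#'
#' Relative quantification of a target amplicon against a single-copy
#' reference amplicon with per-amplicon amplification efficiencies:
#' `CN_s = E_t^(Ct_t,cal - Ct_t,s) / E_r^(Ct_r,cal - Ct_r,s)`,
#' the calibrator sample's copy number being defined as 1.  Replicate Ct
#' values are averaged before exponentiation.
#'
#' @param qpcr data.frame with `sample`, `amplicon`, `replicate`, `ct`.
#' @param efficiency Named numeric vector of per-amplicon efficiencies in
#'   (1, 2] (defaults to the table's `"efficiency"` attribute).
#' @param calibrator Sample id whose copy number defines 1.
#' @param target,reference Amplicon ids.
#' @return Named numeric vector of per-sample copy numbers.
#' @export
qpcr_copy_number <- function(qpcr, efficiency = attr(qpcr, "efficiency"),
                             calibrator = "calibrator",
                             target = "target", reference = "reference") {
  if (is.null(efficiency)) stop("amplicon efficiencies are required")
  if (any(efficiency <= 1 | efficiency > 2)) {
    stop("efficiencies must lie in (1, 2]")
  }
  for (amp in c(target, reference)) {
    if (!amp %in% qpcr$amplicon) stop("amplicon missing from table: ", amp)
  }
  if (!calibrator %in% qpcr$sample) stop("calibrator sample missing: ", calibrator)
  mean_ct <- function(amp) {
    sub <- qpcr[qpcr$amplicon == amp, ]
    tapply(sub$ct, sub$sample, mean)
  }
  ct_t <- mean_ct(target)
  ct_r <- mean_ct(reference)
  samples <- intersect(names(ct_t), names(ct_r))
  cn <- efficiency[[target]]^(ct_t[calibrator] - ct_t[samples]) /
    efficiency[[reference]]^(ct_r[calibrator] - ct_r[samples])
  setNames(as.numeric(cn), samples)
}

#' Per-gene expression fold change between sample groups
#'
#' Ratio of group means of size-factor-normalized counts.
#'
#' @param matrix Genes-by-samples RNA count matrix.
#' @param factors Size factors.
#' @param group_a,group_b Disjoint, non-empty sample sets (column names or
#'   indices); the fold change is a over b.
#' @return Named numeric vector of per-gene fold changes (missing where
#'   the group-b mean is zero).
#' @export
expression_fold_change <- function(matrix, factors, group_a, group_b) {
  if (!length(group_a) || !length(group_b)) stop("groups must be non-empty")
  if (length(intersect(group_a, group_b))) stop("groups must be disjoint")
  norm <- sweep(matrix, 2, factors, "/")
  mean_a <- rowMeans(norm[, group_a, drop = FALSE])
  mean_b <- rowMeans(norm[, group_b, drop = FALSE])
  fc <- ifelse(mean_b > 0, mean_a / mean_b, NA_real_)
  setNames(fc, rownames(matrix))
}
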