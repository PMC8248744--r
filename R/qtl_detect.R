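#' Permutation parameters for QTL detection
#'
#' @param n_permutations Number of circular rotations (default 10000).
#' @param fdr Level at which the max-deviation null distribution is cut
#'   (default 0.05).  The threshold construction is an empirical upper
#'   quantile of genome-wide maxima — effectively a family-wise threshold —
#'   but the conventional "FDR" label of this workflow is kept in outputs.
#' @param seed Integer seed for the rotation offsets.
#' @return A `permutation_params` list.
#' @export
permutation_params <- function(n_permutations = 10000, fdr = 0.05, seed = 1L) {
  stopifnot(n_permutations >= 100, fdr > 0, fdr < 1)
  structure(list(n_permutations = as.integer(n_permutations), fdr = fdr,
                 seed = as.integer(seed)),
            class = "permutation_params")
}

#' QTL-interval parameters
#'
#' @param similarity_delta A window is peak-similar when its mean value is
#'   within this distance of the peak value (default 0.005).
#' @param block_len Outward extension from the peak continues while the
#'   most recent block of this many consecutive windows contains at least
#'   one peak-similar window (default 5).
#' @return An `interval_params` list.
#' @export
interval_params <- function(similarity_delta = 0.005, block_len = 5) {
  stopifnot(similarity_delta >= 0, block_len >= 1)
  structure(list(similarity_delta = similarity_delta,
                 block_len = as.integer(block_len)),
            class = "interval_params")
}

#' Differential-expression call cutoffs
#'
#' @param fc_cutoff Minimum absolute fold change (default 2).
#' @param padj_cutoff Maximum adjusted p-value (default 0.05).
#' @return A `deg_params` list.
#' @export
deg_params <- function(fc_cutoff = 2, padj_cutoff = 0.05) {
  stopifnot(fc_cutoff >= 1, padj_cutoff > 0, padj_cutoff <= 1)
  structure(list(fc_cutoff = fc_cutoff, padj_cutoff = padj_cutoff),
            class = "deg_params")
}

#' Concatenate the windowed genome into a ring
#'
#' Chromosomes are concatenated in layout order into a single circle (the
#' end of the last chromosome joins the beginning of the first) so that
#' rotations preserve linkage structure.  Windows missing in every pair are
#' removed from the ring, with their grid positions remembered for
#' inversion.
#'
#' @param track A `paired_diff_track`.
#' @return A `bsa_ring`: per-pair value matrix over retained ring
#'   positions, the retained grid-row `index`, and the grid.
#' @export
circularize <- function(track) {
  stopifnot(inherits(track, "paired_diff_track"))
  idx <- which(track$n_pairs_used > 0)
  if (!length(idx)) stop("empty track: no retained windows")
  structure(list(values = track$values[idx, , drop = FALSE],
                 mean = track$mean[idx],
                 index = idx, grid = track$grid),
            class = "bsa_ring")
}

#' @rdname circularize
#' @param ring A `bsa_ring`.
#' @param values Per-ring-position values to place back on the linear grid.
#' @return Numeric vector over the full window grid (missing off the ring).
#' @export
decircularize <- function(ring, values) {
  out <- rep(NA_real_, nrow(ring$grid))
  out[ring$index] <- values
  out
}

#' Null distribution of maximal deviations under circular rotation
#'
#' Each permutation rotates every pair's difference profile around the ring
#' by an independent uniform offset, averages the rotated profiles across
#' pairs, and records the maximum absolute averaged value.  The
#' significance threshold is the value exceeded by exactly
#' `floor(fdr * n_permutations)` permutation maxima.
#'
#' @param ring A [circularize()] result.
#' @param params A [permutation_params()].
#' @return A `null_max_distribution`: the per-permutation maxima and the
#'   derived `threshold`.
#' @export
permutation_null <- function(ring, params = permutation_params()) {
  stopifnot(inherits(ring, "bsa_ring"))
  n <- nrow(ring$values)
  n_pairs <- ncol(ring$values)
  # doubled vectors make each rotation a contiguous slice
  vals <- ring$values
  vd <- rbind(ifelse(is.na(vals), 0, vals), ifelse(is.na(vals), 0, vals))
  md <- rbind(!is.na(vals), !is.na(vals)) * 1
  maxima <- numeric(params$n_permutations)
  withr::with_seed(params$seed, {
    for (p in seq_len(params$n_permutations)) {
      s <- numeric(n)
      m <- numeric(n)
      off <- sample.int(n, n_pairs, replace = TRUE) - 1L
      for (j in seq_len(n_pairs)) {
        rows <- (off[j] + 1L):(off[j] + n)
        s <- s + vd[rows, j]
        m <- m + md[rows, j]
      }
      maxima[p] <- max(abs(s[m > 0] / m[m > 0]))
    }
  })
  k <- min(floor(params$fdr * params$n_permutations),
           params$n_permutations - 1)
  threshold <- sort(maxima, decreasing = TRUE)[k + 1]
  structure(list(maxima = maxima, threshold = threshold, params = params),
            class = "null_max_distribution")
}

#' @export
print.null_max_distribution <- function(x, ...) {
  cat(sprintf("<null_max_distribution> %d permutations; threshold %.4f at level %.3f\n",
              length(x$maxima), x$threshold, x$params$fdr))
  invisible(x)
}

#' Call QTL from the mean difference track
#'
#' Windows whose absolute mean difference reaches the threshold are
#' significant; each maximal run of contiguous significant windows (runs
#' never span chromosome boundaries) becomes one QTL call with its peak at
#' the window of largest absolute value (leftmost on ties).
#'
#' @param track A `paired_diff_track`.
#' @param threshold Non-negative significance threshold.
#' @return A `qtl_calls` data.frame: one row per call with the peak window
#'   coordinates, peak value, and the first/last grid rows of the run.
#' @export
call_qtls <- function(track, threshold) {
  stopifnot(threshold >= 0)
  sig <- !is.na(track$mean) & abs(track$mean) >= threshold
  calls <- list()
  for (ci in unique(as.character(track$grid$chrom))) {
    rows <- which(as.character(track$grid$chrom) == ci & sig)
    if (!length(rows)) next
    run_id <- cumsum(c(1, diff(rows) != 1))
    for (r in split(rows, run_id)) {
      peak <- r[which.max(abs(track$mean[r]))]
      calls[[length(calls) + 1]] <- data.frame(
        chrom = ci,
        peak_start = track$grid$start[peak],
        peak_end = track$grid$end[peak],
        peak_value = track$mean[peak],
        peak_row = peak, run_first = r[1], run_last = r[length(r)]
      )
    }
  }
  out <- if (length(calls)) do.call(rbind, calls) else
    data.frame(chrom = character(), peak_start = numeric(),
               peak_end = numeric(), peak_value = numeric(),
               peak_row = integer(), run_first = integer(),
               run_last = integer())
  attr(out, "threshold") <- threshold
  class(out) <- c("qtl_calls", "data.frame")
  out
}

#' Sub-threshold subsidiary peaks
#'
#' The top `k` local maxima of the absolute mean track that do not reach
#' the significance threshold, reported without any significance claim.
#' Peaks are greedily selected highest-first with a minimum separation of
#' one full window width.
#'
#' @param track A `paired_diff_track`.
#' @param threshold Significance threshold.
#' @param k Number of subsidiary peaks to report (default 2).
#' @return data.frame of peak windows and values.
#' @export
subsidiary_peaks <- function(track, threshold, k = 2) {
  v <- abs(track$mean)
  ok <- !is.na(v) & v < threshold
  cand <- order(ifelse(ok, v, -Inf), decreasing = TRUE)
  win_w <- ceiling((track$grid$end[1] - track$grid$start[1] + 1) /
                     (track$grid$start[2] - track$grid$start[1]))
  picked <- integer(0)
  for (i in cand) {
    if (!ok[i]) break
    if (length(picked) >= k) break
    if (any(abs(picked - i) <= win_w &
              track$grid$chrom[picked] == track$grid$chrom[i])) next
    picked <- c(picked, i)
  }
  data.frame(chrom = track$grid$chrom[picked],
             start = track$grid$start[picked],
             end = track$grid$end[picked],
             value = track$mean[picked])
}

#' Delineate a QTL interval by peak similarity
#'
#' A window is peak-similar when its mean value lies within
#' `similarity_delta` of the peak value.  Walking outward from the peak in
#' each direction, the extension continues while the most recent block of
#' `block_len` consecutive windows contains at least one peak-similar
#' window; the interval spans from the outermost peak-similar window
#' reached leftward to the outermost reached rightward.
#'
#' @param track A `paired_diff_track`.
#' @param call One row of a [call_qtls()] result.
#' @param params An [interval_params()].
#' @return data.frame `chrom`, `start`, `end` (bp, 1-based inclusive) with
#'   the member grid rows attached as the `"rows"` attribute.
#' @export
qtl_interval <- function(track, call, params = interval_params()) {
  peak <- call$peak_row
  pv <- track$mean[peak]
  chrom <- as.character(track$grid$chrom[peak])
  on_chr <- as.character(track$grid$chrom) == chrom
  similar <- function(i) {
    !is.na(track$mean[i]) && abs(track$mean[i] - pv) <= params$similarity_delta
  }
  walk <- function(step) {
    outer <- peak
    i <- peak + step
    gap <- 0L
    while (i >= 1 && i <= nrow(track$grid) && on_chr[i] &&
             gap < params$block_len) {
      if (similar(i)) {
        outer <- i
        gap <- 0L
      } else {
        gap <- gap + 1L
      }
      i <- i + step
    }
    outer
  }
  left <- walk(-1L)
  right <- walk(1L)
  out <- data.frame(chrom = chrom,
                    start = track$grid$start[left],
                    end = track$grid$end[right])
  attr(out, "rows") <- left:right
  out
}

#' Count differentially expressed genes within QTL intervals
#'
#' A gene is a DEG when its absolute fold change reaches `fc_cutoff` and
#' its adjusted p-value is at most `padj_cutoff`; it lies within an
#' interval when its span overlaps it by at least 1 bp.
#'
#' @param de_table data.frame with `gene_id`, `fc` (signed fold change),
#'   `padj`.
#' @param annotation Gene coordinates (`gene_id`, `chrom`, `start`, `end`,
#'   1-based inclusive).
#' @param intervals data.frame of QTL intervals (`chrom`, `start`, `end`).
#' @param params A [deg_params()].
#' @return List with `per_interval` counts, `total` distinct DEGs in any
#'   interval, `n_deg` genome-wide DEGs, and the fraction `prop_in_intervals`.
#' @export
count_degs_in_intervals <- function(de_table, annotation, intervals,
                                    params = deg_params()) {
  if (anyDuplicated(de_table$gene_id)) stop("duplicate gene IDs in DE table")
  de <- de_table[!is.na(de_table$fc) & !is.na(de_table$padj) &
                   abs(de_table$fc) >= params$fc_cutoff &
                   de_table$padj <= params$padj_cutoff, ]
  genes <- merge(de["gene_id"], annotation, by = "gene_id")
  per <- integer(nrow(intervals))
  hit_any <- character(0)
  for (i in seq_len(nrow(intervals))) {
    on_chr <- genes[as.character(genes$chrom) ==
                      as.character(intervals$chrom[i]), , drop = FALSE]
    if (nrow(on_chr)) {
      ov <- IRanges::findOverlaps(
        IRanges::IRanges(on_chr$start, on_chr$end),
        IRanges::IRanges(intervals$start[i], intervals$end[i]))
      hits <- on_chr$gene_id[unique(S4Vectors::queryHits(ov))]
      per[i] <- length(hits)
      hit_any <- union(hit_any, hits)
    }
  }
  list(per_interval = per, total = length(hit_any), n_deg = nrow(de),
       prop_in_intervals = if (nrow(de)) length(hit_any) / nrow(de) else NA_real_)
}
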