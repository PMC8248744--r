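#' Sliding-window parameters for the DNA allele-frequency scan
#'
#' Defaults follow the mapping workflow this package implements: 75 kb
#' windows advanced in 5 kb steps, with a window retained only when it
#' contains at least 38 usable sites.
#'
#' @param size Window width in bp (default 75000).
#' @param step Step between window starts in bp (default 5000).
#' @param min_sites Minimum sites per retained window (default 38).
#' @return A `window_params` list.
#' @export
window_params <- function(size = 75000, step = 5000, min_sites = 38) {
  stopifnot(step > 0, step <= size, min_sites >= 1)
  structure(list(size = size, step = step, min_sites = min_sites),
            class = "window_params")
}

#' RNA-scan parameters
#'
#' @param min_coverage Minimum RNA read depth, required in both members of
#'   a pair (default 20).
#' @param max_control_major_af Positions are kept only when the major
#'   allele frequency in the control member is strictly below this value
#'   (default 0.95).
#' @param window Non-overlapping window width in bp (default 500000).
#' @return An `rna_scan_params` list.
#' @export
rna_scan_params <- function(min_coverage = 20, max_control_major_af = 0.95,
                            window = 500000) {
  stopifnot(min_coverage >= 1, max_control_major_af > 0.5,
            max_control_major_af <= 1, window > 0)
  structure(list(min_coverage = min_coverage,
                 max_control_major_af = max_control_major_af,
                 window = window),
            class = "rna_scan_params")
}

# The window grid over a genome layout: windows start at position 1,
# advance by `step`, and are kept only when they fit entirely on the
# chromosome (trailing partial windows are dropped, keeping the width and
# the min_sites criterion constant genome-wide).
window_grid <- function(layout, size, step) {
  per_chrom <- lapply(seq_len(nrow(layout)), function(i) {
    len <- layout$length[i]
    if (len < size) return(NULL)
    starts <- seq(1, len - size + 1, by = step)
    data.frame(chrom = layout$chrom[i], start = starts,
               end = starts + size - 1)
  })
  do.call(rbind, per_chrom)
}

#' Windowed mean of per-site values along the genome
#'
#' Computes the unweighted mean of site values within each sliding window.
#' Windows with fewer than `min_sites` sites carry a missing value.
#'
#' @param sites data.frame with `chrom`, `pos` (1-based) and the value
#'   column named by `value_col`; must be sorted by position within each
#'   chromosome.
#' @param layout A [genome_layout()].
#' @param params A [window_params()].
#' @param value_col Name of the value column (default `"freq"`).
#' @return A `window_track` data.frame: `chrom`, `start`, `end`,
#'   `n_sites`, `value`.
#' @export
windowed_frequency <- function(sites, layout, params = window_params(),
                               value_col = "freq") {
  grid <- window_grid(layout, params$size, params$step)
  if (is.null(grid)) stop("no chromosome can hold a full window")
  grid$n_sites <- 0L
  grid$value <- NA_real_
  for (ci in unique(as.character(grid$chrom))) {
    on_chr <- sites[as.character(sites$chrom) == ci, , drop = FALSE]
    gi <- which(as.character(grid$chrom) == ci)
    if (!nrow(on_chr)) next
    if (is.unsorted(on_chr$pos)) stop("sites not sorted by position on chromosome ", ci)
    vals <- on_chr[[value_col]]
    ok <- !is.na(vals)
    pos <- on_chr$pos[ok]
    vals <- vals[ok]
    cs <- c(0, cumsum(vals))
    lo <- findInterval(grid$start[gi] - 1, pos)
    hi <- findInterval(grid$end[gi], pos)
    n <- hi - lo
    grid$n_sites[gi] <- n
    grid$value[gi] <- ifelse(n >= params$min_sites,
                             (cs[hi + 1] - cs[lo + 1]) / n, NA_real_)
  }
  class(grid) <- c("window_track", "data.frame")
  grid
}

same_grid <- function(a, b) {
  nrow(a) == nrow(b) &&
    all(as.character(a$chrom) == as.character(b$chrom)) &&
    all(a$start == b$start) && all(a$end == b$end)
}

#' Per-window selected-minus-control difference
#'
#' @param selected,control `window_track`s on identical grids.
#' @return A `window_track` whose value is `selected - control`
#'   (missing when either member is missing).
#' @export
paired_difference <- function(selected, control) {
  if (!same_grid(selected, control)) stop("window grids differ")
  out <- selected
  out$value <- selected$value - control$value
  out$n_sites <- pmin(selected$n_sites, control$n_sites)
  out
}

#' Average windowed difference tracks across pairs
#'
#' The mean is computed per window over the pairs with a non-missing value
#' there; windows missing in every pair stay missing.
#'
#' @param diffs List of per-pair difference `window_track`s on a common grid.
#' @return A `paired_diff_track`: the grid, the windows-by-pairs value
#'   matrix, the mean track, and `n_pairs_used` per window.
#' @export
average_pairs <- function(diffs) {
  if (!length(diffs)) stop("no pairs supplied")
  grid <- diffs[[1]][, c("chrom", "start", "end")]
  for (d in diffs[-1]) {
    if (!same_grid(diffs[[1]], d)) stop("window grids differ across pairs")
  }
  mat <- vapply(diffs, function(d) d$value, numeric(nrow(grid)))
  if (is.null(dim(mat))) mat <- matrix(mat, ncol = length(diffs))
  n_used <- rowSums(!is.na(mat))
  mean_val <- ifelse(n_used > 0, rowMeans(mat, na.rm = TRUE), NA_real_)
  structure(list(grid = grid, values = mat, mean = mean_val,
                 n_pairs_used = n_used),
            class = "paired_diff_track")
}

#' @export
print.paired_diff_track <- function(x, ...) {
  cat(sprintf("<paired_diff_track> %d windows x %d pairs; mean |value| peak %.3f\n",
              nrow(x$grid), ncol(x$values), max(abs(x$mean), na.rm = TRUE)))
  invisible(x)
}

#' DNA BSA scan across all pairs
#'
#' Convenience wrapper: per pair, windowed transmitted-allele frequencies
#' for the selected and control members of each pair are differenced and
#' the per-pair tracks averaged.
#'
#' @param records Filtered `site_records`.
#' @param pairs Pairs table (`pair`, `selected`, `control`).
#' @param layout A [genome_layout()].
#' @param params A [window_params()].
#' @return A `paired_diff_track`.
#' @export
dna_bsa_scan <- function(records, pairs, layout, params = window_params()) {
  diffs <- lapply(seq_len(nrow(pairs)), function(i) {
    ps <- pair_sites(records, pairs[i, ])
    sel <- windowed_frequency(
      data.frame(chrom = ps$chrom, pos = ps$pos, freq = ps$freq_selected),
      layout, params)
    ctl <- windowed_frequency(
      data.frame(chrom = ps$chrom, pos = ps$pos, freq = ps$freq_control),
      layout, params)
    paired_difference(sel, ctl)
  })
  average_pairs(diffs)
}

#' RNA-based BSA scan
#'
#' Per pair, exonic biallelic positions are kept when read coverage is at
#' least `min_coverage` in both members and the major allele frequency in
#' the control member is below `max_control_major_af`.  The absolute
#' selected-minus-control allele-frequency difference is averaged within
#' non-overlapping windows and then across pairs.
#'
#' @param pools A `pool_counts` of RNA allele counts at exonic positions.
#' @param pairs Pairs table.
#' @param layout A [genome_layout()].
#' @param params An [rna_scan_params()].
#' @return A `paired_diff_track` of mean absolute differences.
#' @export
rna_bsa_scan <- function(pools, pairs, layout, params = rna_scan_params()) {
  wp <- window_params(size = params$window, step = params$window,
                      min_sites = 1)
  diffs <- lapply(seq_len(nrow(pairs)), function(i) {
    sel <- pairs$selected[i]
    ctl <- pairs$control[i]
    dep_s <- pools$ref[, sel] + pools$alt[, sel]
    dep_c <- pools$ref[, ctl] + pools$alt[, ctl]
    f_s <- ifelse(dep_s > 0, pools$alt[, sel] / dep_s, NA_real_)
    f_c <- ifelse(dep_c > 0, pools$alt[, ctl] / dep_c, NA_real_)
    major_c <- pmax(f_c, 1 - f_c)
    keep <- dep_s >= params$min_coverage & dep_c >= params$min_coverage &
      !is.na(major_c) & major_c < params$max_control_major_af
    windowed_frequency(
      data.frame(chrom = pools$sites$chrom[keep],
                 pos = pools$sites$pos[keep],
                 freq = abs(f_s - f_c)[keep]),
      layout, wp)
  })
  average_pairs(diffs)
}
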