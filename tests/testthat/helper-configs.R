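# Small, fast simulation configurations shared across test files.

# Toy three-chromosome genome with one selected locus; runs in ~1 s.
tiny_config <- function(seed = 1L, s = 0.5, h = 0.1, n_pairs = 3L,
                        n_generations = 10L, n_females = 150L,
                        dna_depth_mean = 100) {
  sim_config(
    chromosome_lengths = c(8e5, 5e5, 3e5),
    n_pairs = n_pairs, n_females = n_females,
    n_generations = n_generations,
    causal_loci = if (s > 0) {
      data.frame(chrom = 2L, pos = 2.5e5, s = s, h = h)
    } else {
      data.frame(chrom = integer(), pos = numeric(), s = numeric(),
                 h = numeric())
    },
    # fully neutral genome when s = 0 (no CNV purging either)
    cnv_locus = list(chrom = 2L, start = 249001, end = 263000,
                     copies = if (s > 0) 3L else 1L),
    cnv_cost = if (s > 0) 0.1 else 0,
    cis_eqtl = data.frame(chrom = 1L, pos = 4e5, multiplier = 2),
    dna_depth_mean = dna_depth_mean,
    seed = seed
  )
}

# Drift-only configuration at the reduced scale used for null calibration:
# ~2 Mb genome, 11 pairs, pooled depth 60.
drift_config <- function(seed) {
  sim_config(
    chromosome_lengths = c(1e6, 6.5e5, 3.5e5),
    causal_loci = data.frame(chrom = integer(), pos = numeric(),
                             s = numeric(), h = numeric()),
    cnv_locus = list(chrom = 2L, start = 3e5 + 1, end = 3.14e5, copies = 1L),
    cis_eqtl = NULL,
    dna_depth_mean = 60,
    seed = seed
  )
}

# Informative-site row closest to a bp position (test-side counterpart of
# the simulator's internal lookup).
site_nearest_test <- function(map, chrom, pos) {
  on_chr <- which(map$chrom == chrom)
  on_chr[which.min(abs(map$pos[on_chr] - pos))]
}

# A hand-built window track (for QTL-detection unit tests).
make_track <- function(values, chrom = NULL, start_step = 5000,
                       size = 75000) {
  n <- length(values)
  if (is.null(chrom)) chrom <- rep("1", n)
  starts <- unlist(lapply(split(seq_len(n), factor(chrom, unique(chrom))),
                          function(i) (seq_along(i) - 1) * start_step + 1))
  grid <- data.frame(chrom = chrom, start = starts, end = starts + size - 1)
  structure(list(grid = grid,
                 values = matrix(values, ncol = 1),
                 mean = values,
                 n_pairs_used = as.integer(!is.na(values))),
            class = "paired_diff_track")
}

# Window-track constructor for average_pairs tests.
make_window_track <- function(chrom, start, end, value, n_sites = 50L) {
  structure(data.frame(chrom = chrom, start = start, end = end,
                       n_sites = n_sites, value = value),
            class = c("window_track", "data.frame"))
}
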