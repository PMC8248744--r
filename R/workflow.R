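#' Simulation-to-QTL-calls workflow
#'
#' Lean end-to-end run without file output: simulate the experiment, infer
#' transmitted alleles and apply the segregation filters, compute the
#' paired windowed difference track, derive the permutation threshold on
#' the circularized genome, and call QTL.
#'
#' @param config A [sim_config()].
#' @param window A [window_params()].
#' @param perm A [permutation_params()]; its seed defaults to a substream
#'   of the simulation seed.
#' @param interval An [interval_params()].
#' @return List with the simulation, the mean difference `track`, the
#'   `threshold`, the `calls`, and per-call `intervals`.
#' @export
bsa_qtl_workflow <- function(config,
                             window = window_params(),
                             perm = permutation_params(
                               seed = substream_seed(config$seed, "permutation")),
                             interval = interval_params()) {
  sim <- simulate_experiment(config)
  layout <- layout_from_config(config)
  parents <- data.frame(chrom = sim$founders$sites$chrom,
                        pos = sim$founders$sites$pos,
                        mother_gt = "0/0",
                        strain_gt = sim$founders$sites$strain_genotype)
  records <- assign_transmitted_alleles(parents, sim$dna_sites)
  records <- filter_nonsegregating(records, sim$pairs)
  track <- dna_bsa_scan(records, sim$pairs, layout, window)
  null <- permutation_null(circularize(track), perm)
  calls <- call_qtls(track, null$threshold)
  intervals <- if (nrow(calls)) {
    do.call(rbind, lapply(seq_len(nrow(calls)), function(i) {
      qtl_interval(track, calls[i, ], interval)
    }))
  } else {
    data.frame(chrom = character(), start = numeric(), end = numeric())
  }
  list(sim = sim, track = track, threshold = null$threshold,
       null = null, calls = calls, intervals = intervals)
}
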