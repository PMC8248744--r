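#' Read and write pooled allele-count tables
#'
#' Wide TSV with `chrom`, `pos` and a `<sample>.ref` / `<sample>.alt`
#' column pair per population.  `read_pool_counts(write_pool_counts(x))`
#' is the identity on the data model.
#'
#' @param x A `pool_counts` object.
#' @param path File path.
#' @return `read_pool_counts` returns a `pool_counts` object.
#' @export
write_pool_counts <- function(x, path) {
  stopifnot(inherits(x, "pool_counts"))
  out <- x$sites
  for (s in x$samples) {
    out[[paste0(s, ".ref")]] <- x$ref[, s]
    out[[paste0(s, ".alt")]] <- x$alt[, s]
  }
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_pool_counts
#' @export
read_pool_counts <- function(path) {
  df <- read.table(path, header = TRUE, sep = "\t", check.names = FALSE)
  ref_cols <- grep("\\.ref$", names(df), value = TRUE)
  samples <- sub("\\.ref$", "", ref_cols)
  alt_cols <- paste0(samples, ".alt")
  if (!all(alt_cols %in% names(df))) stop("malformed pool counts file: ", path)
  ref <- as.matrix(df[ref_cols])
  alt <- as.matrix(df[alt_cols])
  colnames(ref) <- colnames(alt) <- samples
  pool_counts(df[c("chrom", "pos")], ref, alt)
}

#' Read pooled allele counts from a VCF
#'
#' Maps biallelic SNP records with per-sample allelic depths (`AD`) to a
#' `pool_counts` object.  Multi-allelic and indel records are skipped with
#' a warning.
#'
#' @param path Path to a VCF file.
#' @return A `pool_counts` object.
#' @export
read_vcf_counts <- function(path) {
  vcf <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(vcf)
  ref <- fix[, "REF"]
  alt <- fix[, "ALT"]
  snp <- nchar(ref) == 1 & nchar(alt) == 1 & !grepl(",", alt)
  if (any(!snp)) {
    warning("skipping ", sum(!snp), " multi-allelic or indel record(s)")
  }
  ad <- vcfR::extract.gt(vcf, "AD")
  if (is.null(ad)) stop("VCF has no AD (allelic depth) field")
  ad <- ad[snp, , drop = FALSE]
  parse_ad <- function(col, i) {
    parts <- strsplit(col, ",", fixed = TRUE)
    as.integer(vapply(parts, function(p) p[i] %||% NA_character_, ""))
  }
  refm <- apply(ad, 2, parse_ad, i = 1L)
  altm <- apply(ad, 2, parse_ad, i = 2L)
  if (is.null(dim(refm))) {
    refm <- matrix(refm, ncol = ncol(ad), dimnames = dimnames(ad))
    altm <- matrix(altm, ncol = ncol(ad), dimnames = dimnames(ad))
  }
  pool_counts(data.frame(chrom = fix[snp, "CHROM"],
                         pos = as.integer(fix[snp, "POS"])),
              refm, altm)
}

#' Read and write gene count matrices
#'
#' TSV with a `gene_id` column followed by one column per sample.
#'
#' @param matrix Genes-by-samples matrix with gene ids as row names.
#' @param path File path.
#' @export
write_counts <- function(matrix, path) {
  df <- data.frame(gene_id = rownames(matrix), matrix,
                   check.names = FALSE, row.names = NULL)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_counts
#' @export
read_counts <- function(path) {
  df <- read.table(path, header = TRUE, sep = "\t", check.names = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df$gene_id
  m
}

#' Read and write BED intervals
#'
#' Internal coordinates are 1-based inclusive; on disk the intervals are
#' BED 0-based half-open, so a write/read round trip preserves spans.
#'
#' @param df data.frame with `chrom`, `start`, `end` (1-based inclusive)
#'   and optional further columns.
#' @param path File path.
#' @export
write_bed <- function(df, path) {
  out <- df
  out$start <- out$start - 1
  first <- c("chrom", "start", "end")
  out <- out[c(first, setdiff(names(out), first))]
  write.table(out, path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' @rdname write_bed
#' @param col_names Names for any columns beyond chrom/start/end.
#' @export
read_bed <- function(path, col_names = NULL) {
  df <- read.table(path, header = FALSE, sep = "\t")
  base <- c("chrom", "start", "end")
  extra <- if (ncol(df) > 3) {
    col_names %||% paste0("V", seq_len(ncol(df) - 3))
  } else {
    character(0)
  }
  names(df) <- c(base, extra)
  df$start <- df$start + 1
  df
}

# Window-track TSV: chrom, start (1-based), end, n_sites, value.
write_track <- function(track, path) {
  write.table(track, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Run the full BSA pipeline on a simulated experiment
#'
#' Executes simulate, site inference, the DNA and RNA scans, permutation
#' thresholding, QTL calling and interval delineation, DEG-overlap
#' counting, CNV/qPCR dosage analysis and the inheritance tests, writing
#' every stage's output under `out_dir` together with a run manifest of
#' per-file checksums.
#'
#' @param config A [sim_config()].
#' @param out_dir Output directory (created if absent).
#' @param window,perm,interval,site_filter,rna,deg Stage parameter objects.
#' @param skip Character vector of stage names to skip (`"rna"`,
#'   `"inheritance"`, `"cnv"`).
#' @return Invisibly, a list with every stage result and the `manifest`.
#' @export
run_pipeline <- function(config, out_dir,
                         window = window_params(),
                         perm = permutation_params(seed = substream_seed(config$seed, "permutation")),
                         interval = interval_params(),
                         site_filter = site_filter_params(),
                         rna = rna_scan_params(),
                         deg = deg_params(),
                         skip = character(0)) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  layout <- layout_from_config(config)
  res <- list(config = config)

  sim <- simulate_experiment(config)
  res$sim <- sim
  write_pool_counts(sim$dna_sites, file.path(out_dir, "dna_site_counts.tsv"))
  write_counts(sim$dna_gene_counts, file.path(out_dir, "dna_gene_counts.tsv"))
  write_counts(sim$rna_gene_counts, file.path(out_dir, "rna_gene_counts.tsv"))
  write_bed(sim$annotation[, c("chrom", "start", "end", "gene_id")],
            file.path(out_dir, "genes.bed"))

  parents <- data.frame(chrom = sim$founders$sites$chrom,
                        pos = sim$founders$sites$pos,
                        mother_gt = "0/0",
                        strain_gt = sim$founders$sites$strain_genotype)
  records <- assign_transmitted_alleles(parents, sim$dna_sites, site_filter)
  records <- filter_nonsegregating(records, sim$pairs, site_filter)
  res$records <- records

  track <- dna_bsa_scan(records, sim$pairs, layout, window)
  res$dna_track <- track
  write_track(data.frame(track$grid, value = track$mean,
                         n_pairs = track$n_pairs_used),
              file.path(out_dir, "dna_mean_track.tsv"))

  ring <- circularize(track)
  null <- permutation_null(ring, perm)
  res$null <- null
  calls <- call_qtls(track, null$threshold)
  res$calls <- calls
  intervals <- do.call(rbind, lapply(seq_len(nrow(calls)), function(i) {
    qtl_interval(track, calls[i, ], interval)
  }))
  if (is.null(intervals)) {
    intervals <- data.frame(chrom = character(), start = numeric(),
                            end = numeric())
  }
  res$intervals <- intervals
  res$subsidiary <- subsidiary_peaks(track, null$threshold)
  write.table(data.frame(threshold = null$threshold,
                         fdr = perm$fdr, n_permutations = perm$n_permutations),
              file.path(out_dir, "threshold.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  if (nrow(calls)) {
    write_bed(data.frame(chrom = intervals$chrom, start = intervals$start,
                         end = intervals$end,
                         peak_value = calls$peak_value),
              file.path(out_dir, "qtl_intervals.bed"))
  }
  res$deg_counts <- count_degs_in_intervals(sim$de_table, sim$annotation,
                                            intervals, deg)

  if (!"rna" %in% skip) {
    rna_track <- rna_bsa_scan(sim$rna_sites, sim$pairs, layout, rna)
    res$rna_track <- rna_track
    write_track(data.frame(rna_track$grid, value = rna_track$mean,
                           n_pairs = rna_track$n_pairs_used),
                file.path(out_dir, "rna_mean_track.tsv"))
  }

  if (!"cnv" %in% skip) {
    sf <- size_factors(sim$dna_gene_counts)
    controls <- sim$pairs$control
    rel <- relative_coverage(sim$dna_gene_counts, sf, controls)
    segs <- call_cnv_segments(rowMeans(rel[, sim$pairs$selected, drop = FALSE]),
                              sim$annotation)
    res$cnv_segments <- segs
    if (nrow(segs)) {
      write_bed(segs[, c("chrom", "start", "end", "copies")],
                file.path(out_dir, "cnv_segments.bed"))
    }
    res$qpcr_cn <- qpcr_copy_number(sim$qpcr)
    rsf <- size_factors(sim$rna_gene_counts)
    res$expression_fc <- expression_fold_change(sim$rna_gene_counts, rsf,
                                                sim$pairs$selected, controls)
    write.table(data.frame(sample = names(res$qpcr_cn),
                           copy_number = res$qpcr_cn),
                file.path(out_dir, "qpcr_copy_number.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
  }

  if (!"inheritance" %in% skip) {
    assays <- emit_inheritance_assays(config)
    fits <- lapply(assays[c("S", "R", "F1a", "F1b")], probit_fit)
    res$inheritance <- list(
      fits = fits,
      classification = classify_inheritance(fits$R, fits$S,
                                            fits$F1a, fits$F1b),
      monogenic = monogenic_test(
        setNames(assays$F1a$dead / assays$F1a$n, assays$F1a$dose),
        setNames(assays$R$dead / assays$R$n, assays$R$dose),
        assays$BC)
    )
  }

  files <- list.files(out_dir, full.names = TRUE)
  manifest <- list(
    tool = "hapbsa",
    version = as.character(utils::packageVersion("hapbsa")),
    seed = config$seed,
    n_pairs = config$n_pairs,
    n_generations = config$n_generations,
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S"),
    checksums = as.list(tools::md5sum(files))
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  res$manifest <- manifest
  invisible(res)
}
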