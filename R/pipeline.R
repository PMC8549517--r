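#' Pipeline configuration
#'
#' Bundles inputs and thresholds for [run_pipeline()]. Exactly one of
#' `sim` (a [sim_config()], for a fully simulated run) or `paths` (a named
#' list of real input files) must be given. All thresholds default to the
#' values used throughout the study: 16-bp exclusive sides, <10% unaligned,
#' <=20-bp overlap, <=5 inserted bases, J regions extended while supported
#' by >=2 reads, 28-bp minimum sides in the microhomology null, 100-kb
#' windows.
#'
#' @param sim A [sim_config()] or `NULL`.
#' @param paths Named list with `wasp_aln`, `host_aln` (12-column tabular
#'   alignments), `segments_gff`, optionally `host_fasta`, `wasp_fasta`,
#'   `reads_mapped_host`; or `NULL`.
#' @param thresholds A [chimera_thresholds()] list.
#' @param min_support J-region extension support ([delineate_j_regions()]).
#' @param ie_scope Junction classes counted as integration events
#'   (see [call_ies()]).
#' @param j_source `"empirical"` (delineated from the data, the study's
#'   approach) or `"annotated"` (simulator's motif intervals).
#' @param null_reads In-silico reads for the microhomology null (0 skips).
#' @param null_min_side Minimum side length in the null.
#' @param window_size Window width for the spatial-randomness test.
#' @param read_length Read length in bp.
#' @param genome_size_mbp Host genome size; computed from sequences when
#'   available.
#' @param seed Integer seed.
#' @param out_dir Output directory (`NULL` = no files written).
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(sim = NULL, paths = NULL,
                            thresholds = chimera_thresholds(),
                            min_support = 2,
                            ie_scope = "j",
                            j_source = c("empirical", "annotated"),
                            null_reads = 0,
                            null_min_side = 28,
                            window_size = 100000,
                            read_length = 150,
                            genome_size_mbp = NULL,
                            seed = 1L,
                            out_dir = NULL) {
  if (is.null(sim) == is.null(paths)) {
    abort("give exactly one of `sim` (simulation) or `paths` (real inputs)")
  }
  if (!is.null(sim)) validate_sim_config(sim)
  if (!is.null(paths)) {
    need <- c("wasp_aln", "host_aln", "segments_gff")
    miss <- setdiff(need, names(paths))
    if (length(miss)) {
      abort(sprintf("paths is missing: %s", paste(miss, collapse = ", ")))
    }
    for (p in unlist(paths[intersect(names(paths),
                                     c(need, "host_fasta", "wasp_fasta"))])) {
      if (!file.exists(p)) abort(sprintf("input not found: %s", p))
    }
  }
  structure(list(sim = sim, paths = paths, thresholds = thresholds,
                 min_support = min_support, ie_scope = ie_scope,
                 j_source = match.arg(j_source),
                 null_reads = null_reads, null_min_side = null_min_side,
                 window_size = window_size, read_length = read_length,
                 genome_size_mbp = genome_size_mbp,
                 seed = as.integer(seed), out_dir = out_dir),
            class = "pipeline_config")
}

#' Run the integration-detection pipeline end to end
#'
#' Simulation mode: generates the dataset, aligns reads to the wasp genome
#' with BLASTN, re-aligns the wasp-hitting reads to the host genome (the
#' two-pass strategy keeps the bulk of host background reads out of the
#' expensive second search), classifies chimeras with the four filters,
#' removes PCR duplicates, delineates J regions, calls and normalises
#' integration events, runs the microhomology null and the Poisson window
#' test. Real-input mode starts from precomputed alignment tables and a
#' segment annotation instead.
#'
#' @param config A [pipeline_config()].
#' @return A list of class `him_report` with elements `chimeras`
#'   (classified, deduplicated), `j_regions`, `category_counts`, `events`,
#'   `stats` (per-sample summary), `mh` (observed/expected comparison or
#'   `NULL`), `windows`, `poisson` ([poisson_randomness_test()] result),
#'   `sim` (the `him_sim`, simulation mode only), and `log` (seed,
#'   thresholds, versions).
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  cfg <- config
  sim <- NULL
  circles <- NULL
  host <- NULL

  if (!is.null(cfg$sim)) {
    sim <- simulate_dataset(cfg$sim)
    segments <- sim$segments
    host <- sim$host
    circles <- sim$circles
    read_length <- cfg$sim$read_length
    wdir <- tempfile("himera_pipe")
    wasp_hits <- align_reads(sim$reads, sim$wasp, genome = "wasp",
                             workdir = file.path(wdir, "wasp"))
    wasp_read_ids <- unique(wasp_hits$read_id)
    host_query <- sim$reads[sim$reads$read_id %in% wasp_read_ids, ]
    host_hits <- align_reads(host_query, sim$host, genome = "host",
                             workdir = file.path(wdir, "host"))
    # mapping totals come from the read-truth table: all background host
    # reads map to the host genome, plus whichever wasp-hitting reads also
    # found a host alignment
    reads_mapped_host <- sum(sim$reads$source_type == "host_bg") +
      length(setdiff(unique(host_hits$read_id),
                     sim$reads$read_id[sim$reads$source_type == "host_bg"]))
    unlink(wdir, recursive = TRUE)
  } else {
    segments <- read_segments_gff(cfg$paths$segments_gff)
    wasp_hits <- parse_alignment_table(cfg$paths$wasp_aln, genome = "wasp")
    host_hits <- parse_alignment_table(cfg$paths$host_aln, genome = "host")
    read_length <- cfg$read_length
    if (!is.null(cfg$paths$host_fasta)) {
      host <- as.character(Biostrings::readDNAStringSet(cfg$paths$host_fasta))
    }
    reads_mapped_host <- cfg$paths$reads_mapped_host %||%
      length(unique(host_hits$read_id))
  }

  cls <- classify_chimeras(select_best_hit(wasp_hits),
                           select_best_hit(host_hits),
                           read_length = read_length,
                           thresholds = cfg$thresholds)
  accepted <- assign_segments(cls[cls$accepted, ], segments)
  dedup <- dedupe_pcr(accepted)

  j_regions <- if (cfg$j_source == "annotated") {
    annotated_j_regions(segments)
  } else {
    delineate_all_j_regions(dedup, segments, min_support = cfg$min_support)
  }
  dedup <- classify_junctions(dedup, segments, j_regions)
  cat_counts <- junction_category_counts(dedup)

  events <- call_ies(dedup, scope = cfg$ie_scope)
  gsize <- cfg$genome_size_mbp %||%
    if (!is.null(host)) genome_size_mbp(host) else NA_real_
  stats <- sample_stats("sample_1", n_ies = nrow(events),
                        reads_mapped_host = max(reads_mapped_host, 1),
                        read_length = read_length,
                        genome_size_mbp = gsize)

  mh <- NULL
  if (cfg$null_reads > 0 && !is.null(circles) && !is.null(host)) {
    expected <- simulate_null_chimeras(circles, host,
                                       n_reads = cfg$null_reads,
                                       read_length = read_length,
                                       min_side = cfg$null_min_side,
                                       seed = derive_seed(cfg$seed, "null"))
    observed <- mh_distribution(
      dedup[dedup$junction_class %in% c("J1", "J2"), ])
    mh <- compare_mh_distributions(observed, expected)
  }

  poisson <- NULL; windows <- NULL
  if (!is.null(host)) {
    windows <- make_windows(setNames(nchar(host), names(host)),
                            window_size = min(cfg$window_size,
                                              max(nchar(host))))
    windows <- window_ie_counts(events, windows)
    if (nrow(windows) >= 2) poisson <- poisson_randomness_test(windows)
  }

  report <- structure(
    list(chimeras = dedup, j_regions = j_regions,
         category_counts = cat_counts, events = events, stats = stats,
         mh = mh, windows = windows, poisson = poisson, sim = sim,
         log = list(seed = cfg$seed, thresholds = cfg$thresholds,
                    ie_scope = cfg$ie_scope, j_source = cfg$j_source,
                    read_length = read_length,
                    package_version = as.character(utils::packageVersion("himera")),
                    n_pcr_duplicates = attr(dedup, "n_removed"))),
    class = "him_report")

  if (!is.null(cfg$out_dir)) write_report(report, cfg$out_dir, segments)
  report
}

write_report <- function(report, dir, segments) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  readr::write_tsv(report$chimeras, file.path(dir, "chimeras.tsv"))
  readr::write_tsv(report$events, file.path(dir, "events.tsv"))
  readr::write_tsv(report$category_counts,
                   file.path(dir, "junction_categories.tsv"))
  readr::write_tsv(report$stats, file.path(dir, "sample_stats.tsv"))
  readr::write_tsv(report$j_regions, file.path(dir, "j_regions.tsv"))
  if (nrow(report$j_regions) > 0) {
    write_j_regions_gff(report$j_regions, segments,
                        file.path(dir, "j_regions.gff3"))
  }
  if (!is.null(report$windows)) {
    w <- as_tibble(report$windows)
    readr::write_tsv(w, file.path(dir, "window_counts.tsv"))
    bed <- tibble(chrom = w$contig, chromStart = w$start - 1L,
                  chromEnd = w$end, name = sprintf("w%d", seq_len(nrow(w))),
                  score = w$count)
    readr::write_tsv(bed, file.path(dir, "windows.bed"), col_names = FALSE)
  }
  if (!is.null(report$mh)) {
    readr::write_tsv(report$mh$table, file.path(dir, "microhomology.tsv"))
  }
  if (!is.null(report$poisson)) {
    readr::write_tsv(report$poisson$occupancy,
                     file.path(dir, "poisson_occupancy.tsv"))
  }
  if (!is.null(report$sim)) write_sim(report$sim, file.path(dir, "sim"))
  summary_lines <- utils::capture.output(print(report))
  writeLines(summary_lines, file.path(dir, "report.txt"))
  invisible(dir)
}

#' @export
print.him_report <- function(x, ...) {
  cat("<him_report>\n")
  cat(sprintf("  chimeric reads (deduplicated): %d (PCR duplicates removed: %s)\n",
              nrow(x$chimeras),
              format(x$log$n_pcr_duplicates %||% NA)))
  cat(sprintf("  integration events: %d (scope %s)\n", nrow(x$events),
              x$log$ie_scope))
  if (nrow(x$stats) > 0) {
    cat(sprintf("  IPMH %.2f; IEs per genome %.1f\n",
                x$stats$ipmh[1], x$stats$ies_per_genome[1]))
  }
  if (!is.null(x$poisson) && !x$poisson$degenerate) {
    cat(sprintf("  window test: lambda %.3f, p %.3g\n",
                x$poisson$lambda, x$poisson$p_value))
  }
  invisible(x)
}
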