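#' Simulation configuration
#'
#' Builds and validates the configuration for the synthetic-data generator.
#' The generator emulates the architecture of a bracovirus-bearing wasp
#' genome and a lepidopteran host genome: proviral segments flanked by
#' identical direct repeat junctions (DRJs), a host integration motif (HIM)
#' composed of J2 + spacer + J1 near the 3' DRJ, circle excision that
#' collapses the two DRJs into one, and HIM-mediated integration that removes
#' the spacer and leaves J1 and J2 at the extremities of the integrated
#' sequence.
#'
#' @param host_length Host genome length in bp.
#' @param wasp_length Wasp genome length in bp.
#' @param n_segments Number of proviral segments to plant.
#' @param him_fraction Fraction of segments carrying a HIM.
#' @param drj_length DRJ length in bp (both copies of a segment are identical).
#' @param spacer_range Inclusive range the per-segment J2-J1 spacer length is
#'   drawn from; the canonical biology puts it at 41-73 bp.
#' @param j_length Length of each of the J1 and J2 sub-motifs, in bp. The two
#'   motifs are conserved across segments up to `j_divergence`.
#' @param j_divergence Fraction of J-motif positions mutated per segment
#'   relative to the shared canonical motif. Keeps motifs recognisably
#'   conserved while letting short junction-spanning alignments identify
#'   their segment of origin.
#' @param segment_body Inclusive range for the length of the unique circle
#'   body between the DRJs (excluding DRJ/HIM), in bp.
#' @param read_length Read length in bp (single-end reads).
#' @param depth_host,depth_wasp Fold-coverage of background (non-chimeric)
#'   reads over the host and wasp genomes.
#' @param depth_junction Expected number of reads generated across each
#'   integration junction (junction-spanning fragments are drawn uniformly
#'   over all read placements covering the junction).
#' @param n_integrations_per_segment Integrations simulated per HIM-bearing
#'   segment; recycled across segments, so a vector gives per-segment counts.
#' @param microhomology_probs Probability distribution over requested
#'   J1-side junction microhomology lengths `0:(length-1)`. Defaults to a
#'   distribution concentrated on 0-5 bp.
#' @param pcr_dup_rate Fraction of reads duplicated exactly (PCR duplicates).
#' @param error_rate Per-base substitution probability.
#' @param gc GC content of all random sequence.
#' @param cut_offset_j1,cut_offset_j2 Canonical cut positions relative to the
#'   J1 start and J2 end (0 = exactly at the motif/spacer boundary, so that
#'   the lost piece is exactly the spacer). Fixed per run: junctions without
#'   microhomology then all fall at the same position, as expected for a
#'   site-specific recombinase.
#' @param segment_copy_number Relative circle abundance per segment
#'   (recycled); multiplies `depth_circles` for reads drawn from excised
#'   circles, emulating non-integrated circle load.
#' @param depth_circles Base fold-coverage for reads drawn from excised
#'   circle sequences (0 disables circle-derived reads).
#' @param seed Integer seed; all randomness in the generator derives from it.
#'
#' @return A validated list of class `sim_config`.
#' @export
#' @examples
#' cfg <- sim_config(n_segments = 2, host_length = 2e4, wasp_length = 2e4,
#'                   depth_host = 2, depth_wasp = 2, seed = 1)
sim_config <- function(host_length = 2e5,
                       wasp_length = 1e5,
                       n_segments = 16,
                       him_fraction = 1,
                       drj_length = 100,
                       spacer_range = c(41L, 73L),
                       j_length = 30,
                       j_divergence = 0.25,
                       segment_body = c(1200L, 2200L),
                       read_length = 150,
                       depth_host = 30,
                       depth_wasp = 30,
                       depth_junction = 30,
                       n_integrations_per_segment = 12,
                       microhomology_probs = NULL,
                       pcr_dup_rate = 0.05,
                       error_rate = 0,
                       gc = 0.5,
                       cut_offset_j1 = 0,
                       cut_offset_j2 = 0,
                       segment_copy_number = 1,
                       depth_circles = 0,
                       seed = 1L) {
  if (is.null(microhomology_probs)) {
    microhomology_probs <- c(0.45, 0.25, 0.13, 0.08, 0.05, 0.04, rep(0, 8))
  }
  microhomology_probs <- microhomology_probs / sum(microhomology_probs)
  cfg <- list(
    host_length = as.integer(host_length),
    wasp_length = as.integer(wasp_length),
    n_segments = as.integer(n_segments),
    him_fraction = him_fraction,
    drj_length = as.integer(drj_length),
    spacer_range = as.integer(spacer_range),
    j_length = as.integer(j_length),
    j_divergence = j_divergence,
    segment_body = as.integer(segment_body),
    read_length = as.integer(read_length),
    depth_host = depth_host,
    depth_wasp = depth_wasp,
    depth_junction = depth_junction,
    n_integrations_per_segment = as.integer(n_integrations_per_segment),
    microhomology_probs = microhomology_probs,
    pcr_dup_rate = pcr_dup_rate,
    error_rate = error_rate,
    gc = gc,
    cut_offset_j1 = as.integer(cut_offset_j1),
    cut_offset_j2 = as.integer(cut_offset_j2),
    segment_copy_number = segment_copy_number,
    depth_circles = depth_circles,
    seed = as.integer(seed)
  )
  validate_sim_config(cfg)
  structure(cfg, class = "sim_config")
}

validate_sim_config <- function(cfg) {
  stopifnot(
    is_count(cfg$host_length), is_count(cfg$wasp_length),
    is_count(cfg$n_segments), is_count(cfg$drj_length),
    is_count(cfg$read_length), cfg$read_length >= 32,
    length(cfg$spacer_range) == 2, cfg$spacer_range[1] <= cfg$spacer_range[2],
    cfg$spacer_range[1] >= 1,
    is_prob(cfg$him_fraction), is_prob(cfg$pcr_dup_rate),
    is_prob(cfg$error_rate), is_prob(cfg$gc), is_prob(cfg$j_divergence),
    is_prob(cfg$microhomology_probs),
    abs(sum(cfg$microhomology_probs) - 1) < 1e-8,
    all(cfg$n_integrations_per_segment >= 0),
    cfg$depth_host >= 0, cfg$depth_wasp >= 0, cfg$depth_junction >= 0,
    all(cfg$segment_copy_number > 0), cfg$depth_circles >= 0,
    is_count(abs(cfg$seed))
  )
  if (cfg$read_length < 2 * 16) {
    abort("read_length must be at least 32 bp for chimeras to be detectable")
  }
  invisible(cfg)
}

#' @export
print.sim_config <- function(x, ...) {
  cat("<sim_config>\n")
  cat(sprintf("  genomes: host %s bp, wasp %s bp, %d segments (HIM fraction %.2f)\n",
              format(x$host_length, big.mark = ","),
              format(x$wasp_length, big.mark = ","),
              x$n_segments, x$him_fraction))
  cat(sprintf("  reads: %d bp, depth host %g / wasp %g, %g per junction, error %g, PCR dup %g\n",
              x$read_length, x$depth_host, x$depth_wasp, x$depth_junction,
              x$error_rate, x$pcr_dup_rate))
  cat(sprintf("  integrations: %s per segment, mh P(0..%d), seed %d\n",
              paste(x$n_integrations_per_segment, collapse = "/"),
              length(x$microhomology_probs) - 1L, x$seed))
  invisible(x)
}
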