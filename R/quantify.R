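#' Call integration events from deduplicated chimeras
#'
#' Groups deduplicated chimeric reads into unique integration events, one
#' event per unique (segment, host contig, host junction position,
#' orientation, junction side); the supporting-read count of an event is
#' its group size. By default only junctions falling in the J1/J2 regions
#' are counted — the parsimonious choice used for quantification — while
#' `scope` widens the calling to all HIM junctions or to every chimera.
#'
#' @param chimeras Deduplicated, junction-classified chimeras
#'   ([dedupe_pcr()] then [classify_junctions()]).
#' @param scope `"j"` (J1/J2 only, default), `"him"` (any junction inside a
#'   HIM) or `"all"`.
#' @param merge_tolerance Breakpoint-clustering radius in bp: an event is
#'   absorbed into a better-supported event of the same segment, contig,
#'   orientation and host flank whose host position lies within this
#'   distance. Sequencing errors adjacent to a junction truncate the local
#'   alignment by a base or two and would otherwise surface as spurious
#'   singleton events beside the true one; on clean data the clustering is
#'   a no-op because independent integrations are never this close. `0`
#'   disables it.
#' @return A tibble of events: `segment_id`, `junction_class`,
#'   `host_contig`, `host_position`, `orientation`, `host_flank` (which
#'   side of the junction the host sequence occupies, distinguishing the
#'   two junctions of one insertion), `junction_on_wasp` (modal wasp-side
#'   coordinate), `support`.
#' @export
call_ies <- function(chimeras, scope = c("j", "him", "all"),
                     merge_tolerance = 5) {
  scope <- match.arg(scope)
  ch <- chimeras
  if (!"junction_class" %in% names(ch)) {
    if (scope != "all") {
      abort("chimeras lack junction_class; run classify_junctions() or use scope = \"all\"")
    }
    ch$junction_class <- factor("outside_HIM",
                                levels = c("J1", "J2", "HIM_other",
                                           "outside_HIM"))
  }
  keep <- switch(scope,
                 j = ch$junction_class %in% c("J1", "J2"),
                 him = ch$junction_class %in% c("J1", "J2", "HIM_other"),
                 all = rep(TRUE, nrow(ch)))
  ch <- ch[keep, , drop = FALSE]
  if (nrow(ch) == 0) {
    return(tibble(segment_id = character(), junction_class = factor(),
                  host_contig = character(), host_position = integer(),
                  orientation = character(), junction_on_wasp = integer(),
                  support = integer()))
  }
  if (!"host_flank" %in% names(ch)) ch$host_flank <- NA_character_
  ev <- ch |>
    group_by(.data$segment_id, .data$junction_class,
             host_contig = .data$host_subject_id,
             host_position = .data$junction_on_host,
             .data$orientation, .data$host_flank) |>
    summarise(junction_on_wasp = {
      t <- table(.data$junction_on_circle)
      as.integer(names(t)[which.max(t)])
    }, support = dplyr::n(), .groups = "drop")
  if (merge_tolerance > 0) ev <- merge_nearby_events(ev, merge_tolerance)
  arrange(ev, .data$host_contig, .data$host_position)
}

# support-weighted greedy clustering: within (segment, contig, orientation,
# host flank), each event joins the best-supported retained event within
# `tol` bp; the representative keeps its coordinates and class and gains
# the absorbed support
merge_nearby_events <- function(ev, tol) {
  groups <- split(
    seq_len(nrow(ev)),
    paste(ev$segment_id, ev$host_contig, ev$orientation, ev$host_flank))
  keep <- logical(nrow(ev))
  support <- ev$support
  for (idx in groups) {
    ord <- idx[order(-ev$support[idx], ev$host_position[idx])]
    retained <- integer(0)
    for (i in ord) {
      if (length(retained)) {
        d <- abs(ev$host_position[retained] - ev$host_position[i])
        hit <- which(d <= tol)
        if (length(hit)) {
          tgt <- retained[hit[which.max(support[retained[hit]])]]
          support[tgt] <- support[tgt] + support[i]
          next
        }
      }
      retained <- c(retained, i)
      keep[i] <- TRUE
    }
  }
  ev$support <- support
  ev[keep, , drop = FALSE]
}

#' Integration events per million host-mapped reads (IPMH)
#'
#' @param n_ies Number of integration events.
#' @param reads_mapped_host Reads mapping to the host genome.
#' @return `n_ies / (reads_mapped_host / 1e6)`.
#' @export
#' @examples
#' ipmh(100, 5e7) # 2
ipmh <- function(n_ies, reads_mapped_host) {
  if (any(reads_mapped_host <= 0)) abort("reads_mapped_host must be positive")
  n_ies / (reads_mapped_host / 1e6)
}

#' Average integration events per haploid genome
#'
#' Converts a per-million-mapped-reads rate into events per haploid genome:
#' `(ipmh / read_length) * genome_size_mbp`. With the study's hemocyte
#' numbers (12.5 IPMH, 150-bp reads, 1,021-Mbp genome) this yields ~85.
#'
#' @param ipmh Events per million host-mapped reads.
#' @param read_length Read length in bp.
#' @param genome_size_mbp Haploid genome size in Mbp.
#' @return Events per haploid genome (full precision; round for display).
#' @export
ies_per_genome <- function(ipmh, read_length, genome_size_mbp) {
  if (any(read_length <= 0)) abort("read_length must be positive")
  (ipmh / read_length) * genome_size_mbp
}

#' Haploid genome size in Mbp from sequences or a FASTA file
#'
#' @param x Named character vector of sequences or a FASTA path.
#' @return Total length in mega-base pairs.
#' @export
genome_size_mbp <- function(x) {
  if (length(x) == 1 && nchar(x) < 1000 && file.exists(x)) {
    x <- as.character(Biostrings::readDNAStringSet(x))
  }
  sum(nchar(x)) / 1e6
}

#' Maximum number of cells sequenced at a given haploid depth
#'
#' Each diploid cell contributes two haploid genome copies, so sequencing
#' at `depth` fold haploid coverage can have sampled at most
#' `floor(depth / ploidy)` cells at every locus.
#'
#' @param depth Haploid sequencing depth (fold).
#' @param ploidy Cell ploidy (2 for diploid).
#' @return Maximum cell count.
#' @export
max_cells_sequenced <- function(depth, ploidy = 2) {
  floor(depth / ploidy)
}

#' Mean fold-coverage of a segment from a depth track
#'
#' @param track Depth track tibble with `contig`, `start`, `end`, `depth`
#'   (0-based half-open intervals, bedGraph-style).
#' @param seg One-row annotation with `contig`, `start`, `end` (1-based
#'   inclusive).
#' @return Arithmetic mean of the per-base depth over the segment.
#' @export
segment_depth <- function(track, seg) {
  stopifnot(nrow(seg) == 1)
  if (seg$end < seg$start) abort("empty segment")
  lo <- seg$start - 1L  # 0-based
  hi <- seg$end
  tr <- track[track$contig == seg$contig & track$end > lo & track$start < hi, ]
  covered <- sum(pmin(tr$end, hi) - pmax(tr$start, lo))
  if (covered < hi - lo) {
    abort("depth track does not cover the whole segment")
  }
  w <- pmin(tr$end, hi) - pmax(tr$start, lo)
  sum(w * tr$depth) / (hi - lo)
}

#' Build a depth track from a read-truth table
#'
#' Computes exact per-base coverage on one contig from simulated read
#' intervals and run-length-encodes it into a bedGraph-style track.
#'
#' @param reads Read tibble with `source`, `start`, `end`.
#' @param contig Contig/source name to tabulate.
#' @param length Contig length in bp.
#' @return A depth-track tibble (`contig`, `start`, `end`, `depth`,
#'   0-based half-open).
#' @export
depth_track_from_reads <- function(reads, contig, length) {
  r <- reads[reads$source == contig, ]
  delta <- numeric(length + 1L)
  if (nrow(r) > 0) {
    s <- pmax(1L, r$start); e <- pmin(length, r$end)
    for (i in seq_along(s)) {
      delta[s[i]] <- delta[s[i]] + 1
      delta[e[i] + 1L] <- delta[e[i] + 1L] - 1
    }
  }
  depth <- cumsum(delta[seq_len(length)])
  rle_d <- rle(depth)
  ends <- cumsum(rle_d$lengths)
  tibble(contig = contig, start = c(0L, head(ends, -1)), end = ends,
         depth = rle_d$values)
}

#' Correlation between per-segment depth and integration-event counts
#'
#' Spearman rank correlation between mean segment sequencing depth and
#' per-segment IE counts, plus the per-segment depth/IE ratio table. A
#' strong positive correlation is the signature that integration rates
#' track circle abundance.
#'
#' @param depths Named numeric vector (or tibble `segment_id`/`depth`) of
#'   per-segment mean depths.
#' @param ie_counts Named numeric vector (or tibble `segment_id`/`n_ies`)
#'   of per-segment event counts.
#' @return An object of class `ie_depth_cor`: list with `rho`, `p_value`,
#'   `n`, and `ratios` (per-segment depth, IEs and depth/IE ratio).
#' @export
depth_ie_correlation <- function(depths, ie_counts) {
  if (is.data.frame(depths)) depths <- setNames(depths$depth, depths$segment_id)
  if (is.data.frame(ie_counts)) {
    ie_counts <- setNames(ie_counts$n_ies, ie_counts$segment_id)
  }
  segs <- intersect(names(depths), names(ie_counts))
  if (length(segs) < 4) abort("need at least 4 segments")
  d <- depths[segs]; n <- ie_counts[segs]
  if (length(unique(d)) == 1 || length(unique(n)) == 1) {
    warn("constant vector: Spearman rho is undefined")
    res <- list(rho = NA_real_, p_value = NA_real_, n = length(segs),
                degenerate = TRUE)
  } else {
    ct <- suppressWarnings(cor.test(d, n, method = "spearman"))
    res <- list(rho = unname(ct$estimate), p_value = ct$p.value,
                n = length(segs), degenerate = FALSE)
  }
  res$ratios <- tibble(segment_id = segs, depth = unname(d),
                       n_ies = unname(n),
                       depth_per_ie = unname(ifelse(n > 0, d / n, NA_real_)))
  structure(res, class = "ie_depth_cor")
}

#' @export
print.ie_depth_cor <- function(x, ...) {
  cat(sprintf("<ie_depth_cor> Spearman rho = %.3f (p = %.3g, n = %d segments)\n",
              x$rho, x$p_value, x$n))
  invisible(x)
}

#' Expected chimeras outside HIMs from a conserved-exon baseline
#'
#' Scales a baseline chimera count observed over single-copy conserved gene
#' exons to a circle by the ratio of (length x mean depth) products, giving
#' the number of chimeric reads expected on the circle if chimera formation
#' were a generic property of any sequence at that abundance.
#'
#' @param busco_exon_total_bp Total exon length of the baseline gene set.
#' @param busco_mean_depth Mean depth over those exons.
#' @param observed_busco_chimeras Chimeras observed on the baseline.
#' @param circle_length_bp,circle_mean_depth Circle length and mean depth.
#' @return Expected chimera count for the circle.
#' @export
expected_outside_him <- function(busco_exon_total_bp, busco_mean_depth,
                                 observed_busco_chimeras,
                                 circle_length_bp, circle_mean_depth) {
  if (busco_exon_total_bp <= 0 || busco_mean_depth <= 0) {
    abort("baseline length and depth must be positive")
  }
  observed_busco_chimeras * (circle_length_bp * circle_mean_depth) /
    (busco_exon_total_bp * busco_mean_depth)
}

#' Per-sample summary statistics
#'
#' @param sample_id Sample label.
#' @param n_ies Number of integration events called.
#' @param reads_mapped_host,reads_mapped_wasp Mapping totals.
#' @param read_length Read length in bp.
#' @param genome_size_mbp Host genome size in Mbp.
#' @return A one-row tibble with `ipmh` and `ies_per_genome` filled in.
#' @export
sample_stats <- function(sample_id, n_ies, reads_mapped_host,
                         reads_mapped_wasp = NA_integer_,
                         read_length = 150, genome_size_mbp = NA_real_) {
  ip <- ipmh(n_ies, reads_mapped_host)
  tibble(sample_id = sample_id, n_ies = n_ies,
         reads_mapped_host = reads_mapped_host,
         reads_mapped_wasp = reads_mapped_wasp,
         read_length = read_length, genome_size_mbp = genome_size_mbp,
         ipmh = ip,
         ies_per_genome = ies_per_genome(ip, read_length, genome_size_mbp))
}
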