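#' Search a genome for motif occurrences
#'
#' Local similarity search (BLASTN) of a motif library against a genome,
#' both strands, reported on forward-strand 1-based inclusive coordinates.
#'
#' @param genome Named character vector of contig sequences (or FASTA path).
#' @param motifs Named character vector of motif sequences (or FASTA path).
#' @param evalue E-value cutoff (1e-6, the conventional motif-search
#'   stringency).
#' @param min_identity Minimum percent identity retained.
#' @param max_target_seqs BLAST `-max_target_seqs`.
#' @param word_size BLAST word size (7 suits short motifs).
#' @return A tibble of motif hits: `motif_id`, `contig`, `start`, `end`
#'   (forward-strand, `start <= end`), `strand`, `percent_identity`,
#'   `motif_start`, `motif_end` (interval covered on the motif),
#'   `motif_len`, `bitscore`.
#' @export
search_motifs <- function(genome, motifs, evalue = 1e-6, min_identity = 0,
                          max_target_seqs = 500, word_size = 7) {
  if (is.character(genome) && length(genome) == 1 && file.exists(genome)) {
    genome <- as.character(Biostrings::readDNAStringSet(genome))
  }
  if (is.character(motifs) && length(motifs) == 1 && file.exists(motifs)) {
    motifs <- as.character(Biostrings::readDNAStringSet(motifs))
  }
  if (length(motifs) == 0) abort("motif library is empty")
  if (length(genome) == 0 || all(!nzchar(genome))) abort("genome is empty")
  hits <- align_reads(motifs, genome, task = "blastn",
                      word_size = word_size, evalue = evalue,
                      max_target_seqs = max_target_seqs)
  mlen <- tibble(read_id = names(motifs), motif_len = nchar(motifs))
  hits |>
    left_join(mlen, by = "read_id") |>
    filter(.data$percent_identity >= min_identity) |>
    mutate(start = pmin(.data$sbj_start, .data$sbj_end),
           end = pmax(.data$sbj_start, .data$sbj_end)) |>
    select(motif_id = "read_id", contig = "subject_id",
           "start", "end", "strand", "percent_identity",
           motif_start = "read_start", motif_end = "read_end",
           "motif_len", "bitscore") |>
    arrange(.data$contig, .data$start)
}

# classify a HIM-motif hit as covering essentially one side of the spacer:
# >= hi_frac of the J motif on one side and <= lo_frac of the one on the
# other. `j2_end`/`j1_start` delimit the two J motifs on the HIM query.
half_him_type <- function(hits, j2_end, j1_start, hi_frac = 0.8,
                          lo_frac = 0.2) {
  ov <- function(lo, hi) {
    pmax(0L, pmin(hits$motif_end, hi) - pmax(hits$motif_start, lo) + 1L)
  }
  left_frac <- ov(1L, j2_end) / j2_end
  right_frac <- ov(j1_start, hits$motif_len) /
    (hits$motif_len - j1_start + 1L)
  dplyr::case_when(
    left_frac >= hi_frac & right_frac <= lo_frac ~ "J2_half",
    right_frac >= hi_frac & left_frac <= lo_frac ~ "J1_half",
    .default = "full_or_partial"
  )
}

#' Call HIM-mediated (Hdp) and rearranged (Rdp) duplications
#'
#' Reproduces the duplication-detection logic on motif-search output. An
#' integrated (duplicated) circle copy looks like the host-genome insertion
#' product: the J1 motif at one extremity, the J2 motif at the other, no
#' DRJ at either extremity (the single internal DRJ retained from
#' circularisation is permitted). A rearranged duplication (Rdp) is a
#' segment-homologous region with exactly one internal DRJ hit, no DRJs at
#' its extremities and no flanking J1/J2 half-motifs. Intact proviral
#' segments (DRJs at both extremities) are never called.
#'
#' @param him_hits Hits of full HIM motifs ([search_motifs()]), with the
#'   per-motif J-motif limits given by `him_boundaries`.
#' @param junction_hits Optional hits of HIM-to-flank junction queries;
#'   when provided, an Hdp call requires a junction hit overlapping each
#'   half-HIM hit (within `slack`).
#' @param drj_hits Hits of the DRJ library.
#' @param segment_hits Optional hits of full segment sequences; required
#'   for Rdp detection (ignored otherwise).
#' @param him_boundaries Data frame with `motif_id`, `j2_end`, `j1_start`:
#'   the positions on each HIM query where the J2 motif ends and the J1
#'   motif begins (the spacer lies between them).
#' @param slack Coordinate fuzziness tolerated when intersecting the
#'   different search outputs (alignment ends are not base-precise).
#' @param max_span Maximum Hdp length in bp.
#' @return A tibble of duplication calls: `parent_segment_id`, `contig`,
#'   `start`, `end`, `kind` (`"Hdp"`/`"Rdp"`), `strand`, `n_evidence`.
#' @export
call_him_duplications <- function(him_hits, junction_hits = NULL, drj_hits,
                                  segment_hits = NULL, him_boundaries,
                                  slack = 10, max_span = 20000) {
  calls <- list()
  if (nrow(him_hits) > 0) {
    bidx <- match(him_hits$motif_id, him_boundaries$motif_id)
    him_hits$half <- half_him_type(
      him_hits, j2_end = him_boundaries$j2_end[bidx],
      j1_start = him_boundaries$j1_start[bidx])
    halves <- him_hits[him_hits$half != "full_or_partial", , drop = FALSE]
    if (nrow(halves) > 1) {
      for (ct in unique(halves$contig)) {
        h <- halves[halves$contig == ct, ]
        for (i in seq_len(nrow(h))) {
          for (k in seq_len(nrow(h))) {
            a <- h[i, ]; b <- h[k, ]
            if (a$start >= b$start || a$strand != b$strand) next
            span <- b$end - a$start + 1L
            if (span > max_span) next
            # orientation fixes which half must sit on which side
            ok_order <- if (a$strand == "+") {
              a$half == "J1_half" && b$half == "J2_half"
            } else {
              a$half == "J2_half" && b$half == "J1_half"
            }
            if (!ok_order) next
            if (a$motif_id != b$motif_id) next
            # DRJs may sit inside (the retained circle copy) but not at the
            # extremities
            if (nrow(drj_hits) > 0) {
              d <- drj_hits[drj_hits$contig == ct, ]
              at_edge <- d$start <= a$start + slack & d$end >= a$start - slack |
                d$start <= b$end + slack & d$end >= b$end - slack
              if (any(at_edge)) next
            }
            if (!is.null(junction_hits) && nrow(junction_hits) > 0) {
              j <- junction_hits[junction_hits$contig == ct, ]
              covers <- function(hit) {
                any(j$start <= hit$end + slack & j$end >= hit$start - slack)
              }
              if (!covers(a) || !covers(b)) next
            }
            calls[[length(calls) + 1L]] <- tibble(
              parent_segment_id = parent_of(a$motif_id),
              contig = ct, start = a$start, end = b$end,
              kind = "Hdp", strand = a$strand,
              n_evidence = 2L + as.integer(!is.null(junction_hits)))
          }
        }
      }
    }
  }

  if (!is.null(segment_hits) && nrow(segment_hits) > 0) {
    # chain nearby co-linear hits of one segment query into candidate
    # regions, and keep only chains covering most of the query
    regions <- segment_hits |>
      arrange(.data$motif_id, .data$contig, .data$strand, .data$start) |>
      group_by(.data$motif_id, .data$contig, .data$strand) |>
      mutate(chain = cumsum(c(TRUE, .data$start[-1] >
                                cummax(.data$end)[-dplyr::n()] + 500L))) |>
      group_by(.data$chain, .add = TRUE) |>
      summarise(start = min(.data$start), end = max(.data$end),
                coverage = sum(.data$motif_end - .data$motif_start + 1L) /
                  .data$motif_len[1],
                .groups = "drop") |>
      filter(.data$end - .data$start + 1L <= max_span,
             .data$coverage >= 0.8)
    him_all <- him_hits
    for (i in seq_len(nrow(regions))) {
      r <- regions[i, ]
      d <- drj_hits[drj_hits$contig == r$contig &
                      drj_hits$end >= r$start - slack &
                      drj_hits$start <= r$end + slack, , drop = FALSE]
      internal <- d$start > r$start + slack & d$end < r$end - slack
      if (sum(internal) != 1L || any(!internal)) next
      if (nrow(him_all) > 0) {
        flank_him <- him_all$contig == r$contig &
          (abs(him_all$start - r$start) <= slack |
             abs(him_all$end - r$end) <= slack)
        if (any(flank_him)) next
      }
      calls[[length(calls) + 1L]] <- tibble(
        parent_segment_id = parent_of(r$motif_id),
        contig = r$contig, start = r$start, end = r$end,
        kind = "Rdp", strand = r$strand, n_evidence = 1L + sum(internal))
    }
  }
  if (length(calls) == 0) {
    return(tibble(parent_segment_id = character(), contig = character(),
                  start = integer(), end = integer(), kind = character(),
                  strand = character(), n_evidence = integer()))
  }
  distinct(bind_rows(calls))
}

# "HIM_S7" / "DRJ_S7" / "S7" -> "S7"
parent_of <- function(motif_id) {
  sub("^(HIM_|DRJ_|SEG_|segment_|circle_)", "", motif_id)
}
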