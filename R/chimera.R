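#' Thresholds for chimeric-read classification
#'
#' The four filters applied to a read aligning on both genomes: (i) at least
#' `min_side` bases aligning exclusively on each genome; (ii) fewer than
#' `max_unaligned_frac` of the read bases aligning to neither genome
#' (strict); (iii) at most `max_overlap` bases aligning simultaneously on
#' both genomes (the junction microhomology); (iv) at most `max_insert`
#' non-templated bases between the two alignments.
#'
#' @param min_side Minimum exclusive bases per genome.
#' @param max_unaligned_frac Maximum fraction of the read aligned to neither
#'   genome (exclusive bound).
#' @param max_overlap Maximum doubly-aligned bases.
#' @param max_insert Maximum inserted bases between the alignments.
#' @return A named list of thresholds.
#' @export
chimera_thresholds <- function(min_side = 16, max_unaligned_frac = 0.10,
                               max_overlap = 20, max_insert = 5) {
  stopifnot(min_side > 0, max_unaligned_frac > 0, max_overlap >= 0,
            max_insert >= 0)
  list(min_side = min_side, max_unaligned_frac = max_unaligned_frac,
       max_overlap = max_overlap, max_insert = max_insert)
}

#' Keep the single best alignment per read (per genome)
#'
#' Highest bit score wins; ties break on higher percent identity, then
#' lexicographically lowest subject id, then lowest subject start, so the
#' choice is deterministic.
#'
#' @param hits Alignment-hit tibble from [parse_alignment_table()] /
#'   [align_reads()]. If a `genome` column is present, selection is per
#'   (read, genome).
#' @return A tibble with one row per read (and genome).
#' @export
select_best_hit <- function(hits) {
  if (nrow(hits) == 0) return(hits)
  keys <- intersect(c("read_id", "genome"), names(hits))
  hits |>
    mutate(.smin = pmin(.data$sbj_start, .data$sbj_end)) |>
    arrange(across(all_of(keys)), desc(.data$bitscore),
            desc(.data$percent_identity), .data$subject_id, .data$.smin) |>
    group_by(across(all_of(keys))) |>
    slice(1) |>
    ungroup() |>
    select(-".smin")
}

#' Classify reads aligning on both genomes as chimeric or not
#'
#' Takes the best wasp-genome and host-genome alignment of each read and
#' applies the four chimera filters (see [chimera_thresholds()]). For
#' accepted reads the junction geometry is measured: the doubly-aligned
#' overlap (junction microhomology), any inserted non-templated bases, and
#' the junction coordinates. Following the study convention, the junction
#' position on each genome is the alignment end coordinate nearest the
#' junction, regardless of the presence of any overlap.
#'
#' @param wasp_hits,host_hits One best hit per read on each genome
#'   (see [select_best_hit()]); reads present in only one table are labelled
#'   `single_genome`.
#' @param read_length Read length in bp (single value or a tibble
#'   `read_id`/`read_length` for mixed lengths).
#' @param thresholds A [chimera_thresholds()] list.
#' @return A tibble with one row per read appearing in either table:
#'   `accepted`, `reason` (`NA` for accepted reads), the per-read base
#'   partition (`wasp_only`, `host_only`, `overlap_len`, `insert_len`,
#'   `unaligned`), junction coordinates `junction_on_wasp` /
#'   `junction_on_host`, relative `orientation` (`"+"` when the two
#'   alignments are on the same strand), and subject intervals on both
#'   genomes (used for PCR deduplication).
#' @export
classify_chimeras <- function(wasp_hits, host_hits, read_length = 150,
                              thresholds = chimera_thresholds()) {
  if (!"strand" %in% names(wasp_hits)) wasp_hits <- normalise_hits(wasp_hits)
  if (!"strand" %in% names(host_hits)) host_hits <- normalise_hits(host_hits)
  w <- prefix_cols(wasp_hits, "wasp_")
  h <- prefix_cols(host_hits, "host_")
  both <- dplyr::inner_join(w, h, by = "read_id")
  only <- bind_rows(
    dplyr::anti_join(w, h, by = "read_id"),
    dplyr::anti_join(h, w, by = "read_id"))
  if (is.data.frame(read_length)) {
    both <- left_join(both, read_length, by = "read_id")
  } else {
    both$read_length <- read_length
  }

  if (nrow(both) > 0) {
    ws <- both$wasp_read_start; we <- both$wasp_read_end
    hs <- both$host_read_start; he <- both$host_read_end
    len_w <- we - ws + 1L
    len_h <- he - hs + 1L
    ov <- pmax(0L, pmin(we, he) - pmax(ws, hs) + 1L)
    ins <- pmax(0L, pmax(ws, hs) - pmin(we, he) - 1L)
    both$wasp_only <- len_w - ov
    both$host_only <- len_h - ov
    both$overlap_len <- ov
    both$insert_len <- ins
    both$unaligned <- both$read_length - (len_w + len_h - ov) - ins

    th <- thresholds
    # `unaligned` (outside the two alignments) and `insert_len` (between
    # them) partition the unmapped bases; filter (ii) bounds their sum --
    # everything mapping to neither genome. Later assignments take
    # precedence, so reasons rank (i) > (ii) > (iii) > (iv).
    reason <- rep(NA_character_, nrow(both))
    reason[both$insert_len > th$max_insert] <- "max_insert"
    reason[both$overlap_len > th$max_overlap] <- "max_overlap"
    reason[both$unaligned + both$insert_len >=
             th$max_unaligned_frac * both$read_length] <- "unaligned"
    reason[both$host_only < th$min_side] <- "min_side_host"
    reason[both$wasp_only < th$min_side] <- "min_side_wasp"
    both$accepted <- is.na(reason)
    both$reason <- reason

    # the junction-proximal read end of each alignment is one of its
    # endpoints, so the subject coordinate is read off directly (exact even
    # for gapped alignments)
    wasp_left <- (ws + we) < (hs + he)
    both$junction_on_wasp <- ifelse(wasp_left, both$wasp_sbj_end,
                                    both$wasp_sbj_start)
    both$junction_on_host <- ifelse(wasp_left, both$host_sbj_start,
                                    both$host_sbj_end)
    both$orientation <- ifelse(both$wasp_strand == both$host_strand, "+", "-")
    both$wasp_first <- wasp_left
    # which side of the junction the host sequence occupies on the host
    # genome: distinguishes the two junctions of one insertion even when
    # they fall on the same host coordinate
    both$host_flank <- ifelse(
      both$junction_on_host == pmax(both$host_sbj_start, both$host_sbj_end),
      "left", "right")
  }
  if (nrow(only) > 0) {
    only$accepted <- FALSE
    only$reason <- "single_genome"
  }
  out <- bind_rows(both, only)
  out$read_id <- as.character(out$read_id)
  arrange(out, .data$read_id)
}

#' Classify a single read pair
#'
#' Scalar convenience wrapper around [classify_chimeras()] for one read.
#'
#' @param read_length Read length in bp.
#' @param wasp_hit,host_hit One-row hit tibbles for the same read.
#' @param thresholds A [chimera_thresholds()] list.
#' @return A one-row classification tibble.
#' @export
classify_chimera <- function(read_length, wasp_hit, host_hit,
                             thresholds = chimera_thresholds()) {
  stopifnot(nrow(wasp_hit) == 1, nrow(host_hit) == 1)
  if (!identical(wasp_hit$read_id, host_hit$read_id)) {
    abort("wasp_hit and host_hit belong to different reads")
  }
  classify_chimeras(wasp_hit, host_hit, read_length, thresholds)
}

prefix_cols <- function(hits, prefix) {
  keep <- setdiff(names(hits), c("read_id", "genome"))
  names(hits)[match(keep, names(hits))] <- paste0(prefix, keep)
  hits
}

#' Remove PCR duplicates among accepted chimeras
#'
#' Independent sequenced fragments virtually never share the exact same
#' alignment boundaries on both genomes, so chimeras identical in subject
#' intervals on both genomes, junction coordinates and relative orientation
#' are collapsed to one representative. The number of removed duplicates is
#' attached as attribute `n_removed`.
#'
#' @param chimeras Accepted-chimera tibble from [classify_chimeras()].
#' @return The deduplicated tibble (first occurrence kept per group).
#' @export
dedupe_pcr <- function(chimeras) {
  if (nrow(chimeras) == 0) {
    attr(chimeras, "n_removed") <- 0L
    return(chimeras)
  }
  key <- intersect(
    c("wasp_subject_id", "wasp_sbj_start", "wasp_sbj_end",
      "host_subject_id", "host_sbj_start", "host_sbj_end",
      "junction_on_wasp", "junction_on_host", "orientation", "host_flank"),
    names(chimeras))
  out <- chimeras |>
    group_by(across(all_of(key))) |>
    slice(1) |>
    ungroup()
  attr(out, "n_removed") <- nrow(chimeras) - nrow(out)
  out
}

#' Assign chimeras to annotated proviral segments
#'
#' Maps each chimera's wasp-side junction coordinate into the segment
#' annotation and converts it to circle coordinates (1 = first base of the
#' retained DRJ). Wasp-genome positions falling in a segment's 3' DRJ wrap
#' onto the single circle DRJ copy. Chimeras whose wasp hit falls outside
#' any annotated segment are retained and flagged (`in_segment = FALSE`);
#' they serve as the outside-segment baseline.
#'
#' @param chimeras Classification tibble (accepted rows are used).
#' @param segments Segment annotation tibble ([gen_genomes()] layout).
#' @param wasp_is_circle Set `TRUE` when alignments were computed against
#'   circle sequences named `circle_<segment_id>` rather than the wasp
#'   genome; coordinates are then already circle coordinates.
#' @return The tibble with `segment_id`, `junction_on_circle` and
#'   `in_segment` columns added.
#' @export
assign_segments <- function(chimeras, segments, wasp_is_circle = FALSE) {
  ch <- chimeras
  if (nrow(ch) == 0) {
    ch$segment_id <- character(0)
    ch$junction_on_circle <- integer(0)
    ch$in_segment <- logical(0)
    return(ch)
  }
  if (wasp_is_circle) {
    ch$segment_id <- sub("^circle_", "", ch$wasp_subject_id)
    ch$junction_on_circle <- ch$junction_on_wasp
    ch$in_segment <- ch$segment_id %in% segments$segment_id
    return(ch)
  }
  seg_at <- function(contig, pos) {
    hit <- which(segments$contig == contig &
                   segments$start <= pos & segments$end >= pos)
    if (length(hit) == 0) NA_integer_ else hit[1]
  }
  idx <- map_int(seq_len(nrow(ch)), function(i) {
    seg_at(ch$wasp_subject_id[i], ch$junction_on_wasp[i])
  })
  ch$segment_id <- ifelse(is.na(idx), NA_character_, segments$segment_id[idx])
  circ <- ifelse(is.na(idx), NA_integer_,
                 ch$junction_on_wasp - segments$start[idx] + 1L)
  # positions inside the 3' DRJ wrap onto the retained DRJ copy
  wrap <- !is.na(idx) & circ > segments$circle_length[idx]
  circ[wrap] <- circ[wrap] - segments$circle_length[idx][wrap]
  ch$junction_on_circle <- circ
  ch$in_segment <- !is.na(idx)
  ch
}
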