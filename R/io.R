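#' Convert a segment annotation to genomic ranges with GFF3 feature types
#'
#' Feature types emitted: `segment`, `DRJ`, `HIM`, `J1`, `J2`, all 1-based
#' inclusive, with `ID`/`Parent` attributes tying sub-features to their
#' segment.
#'
#' @param segments Segment annotation tibble.
#' @return A `GRanges` suitable for `rtracklayer::export(..., "gff3")`.
#' @export
segments_to_granges <- function(segments) {
  rows <- list()
  add <- function(type, id, parent, contig, start, end) {
    tibble(contig = contig, start = start, end = end, type = type,
           ID = id, Parent = parent)
  }
  for (i in seq_len(nrow(segments))) {
    s <- segments[i, ]
    rows[[length(rows) + 1L]] <-
      add("segment", s$segment_id, NA, s$contig, s$start, s$end)
    rows[[length(rows) + 1L]] <-
      add("DRJ", paste0(s$segment_id, "_DRJ5"), s$segment_id, s$contig,
          s$drj5_start, s$drj5_end)
    rows[[length(rows) + 1L]] <-
      add("DRJ", paste0(s$segment_id, "_DRJ3"), s$segment_id, s$contig,
          s$drj3_start, s$drj3_end)
    if (isTRUE(s$has_him)) {
      rows[[length(rows) + 1L]] <-
        add("HIM", paste0(s$segment_id, "_HIM"), s$segment_id, s$contig,
            s$him_start, s$him_end)
      rows[[length(rows) + 1L]] <-
        add("J2", paste0(s$segment_id, "_J2"), s$segment_id, s$contig,
            s$j2_start, s$j2_end)
      rows[[length(rows) + 1L]] <-
        add("J1", paste0(s$segment_id, "_J1"), s$segment_id, s$contig,
            s$j1_start, s$j1_end)
    }
  }
  df <- bind_rows(rows)
  gr <- GenomicRanges::GRanges(
    seqnames = df$contig,
    ranges = IRanges::IRanges(start = df$start, end = df$end),
    strand = "+")
  S4Vectors::mcols(gr)$type <- df$type
  S4Vectors::mcols(gr)$ID <- df$ID
  S4Vectors::mcols(gr)$Parent <- ifelse(is.na(df$Parent), NA_character_,
                                        df$Parent)
  gr
}

#' Read a segment annotation from GFF3
#'
#' Inverse of [segments_to_granges()] + `rtracklayer::export()`: rebuilds
#' the segment tibble (including circle coordinates and canonical cut
#' positions) from `segment`/`DRJ`/`HIM`/`J1`/`J2` features.
#'
#' @param path GFF3 file.
#' @param cut_offset_j1,cut_offset_j2 Canonical cut offsets (see
#'   [sim_config()]).
#' @return A segment annotation tibble.
#' @export
read_segments_gff <- function(path, cut_offset_j1 = 0, cut_offset_j2 = 0) {
  gr <- rtracklayer::import(path, format = "gff3")
  df <- as_tibble(as.data.frame(gr))
  df$Parent <- vapply(df$Parent, function(p) {
    if (length(p) == 0) NA_character_ else as.character(p[[1]])
  }, character(1))
  segs <- df[df$type == "segment", ]
  out <- lapply(seq_len(nrow(segs)), function(i) {
    s <- segs[i, ]
    kids <- df[!is.na(df$Parent) & df$Parent == s$ID, ]
    drj <- kids[kids$type == "DRJ", ]
    drj <- drj[order(drj$start), ]
    him <- kids[kids$type == "HIM", ]
    j1 <- kids[kids$type == "J1", ]
    j2 <- kids[kids$type == "J2", ]
    has_him <- nrow(him) == 1
    tibble(
      segment_id = s$ID, contig = as.character(s$seqnames),
      start = s$start, end = s$end,
      drj_length = if (nrow(drj) > 0) drj$end[1] - drj$start[1] + 1L else NA_integer_,
      drj5_start = drj$start[1], drj5_end = drj$end[1],
      drj3_start = drj$start[nrow(drj)], drj3_end = drj$end[nrow(drj)],
      has_him = has_him,
      him_start = if (has_him) him$start else NA_integer_,
      him_end = if (has_him) him$end else NA_integer_,
      j2_start = if (nrow(j2)) j2$start else NA_integer_,
      j2_end = if (nrow(j2)) j2$end else NA_integer_,
      j1_start = if (nrow(j1)) j1$start else NA_integer_,
      j1_end = if (nrow(j1)) j1$end else NA_integer_,
      spacer_length = if (has_him && nrow(j1) && nrow(j2)) {
        j1$start - j2$end - 1L
      } else NA_integer_
    )
  })
  out <- bind_rows(out)
  out |>
    mutate(
      circle_length = .data$end - .data$start + 1L - .data$drj_length,
      him_start_c = .data$him_start - .data$start + 1L,
      him_end_c = .data$him_end - .data$start + 1L,
      j2_start_c = .data$j2_start - .data$start + 1L,
      j2_end_c = .data$j2_end - .data$start + 1L,
      j1_start_c = .data$j1_start - .data$start + 1L,
      j1_end_c = .data$j1_end - .data$start + 1L,
      cut2_c = .data$j2_end_c + as.integer(cut_offset_j2),
      cut1_c = .data$j1_start_c - 1L + as.integer(cut_offset_j1)
    )
}

#' Write a simulated dataset to disk
#'
#' Writes genomes and circles as FASTA, the segment annotation as GFF3,
#' reads as FASTQ, and the truth tables (events, junctions, read truth) as
#' TSV.
#'
#' @param sim A `him_sim` object.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_sim <- function(sim, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_fasta(sim$host, file.path(dir, "host.fasta"))
  write_fasta(sim$wasp, file.path(dir, "wasp.fasta"))
  if (length(sim$circles)) {
    write_fasta(sim$circles, file.path(dir, "circles.fasta"))
  }
  if (nrow(sim$segments) > 0) {
    rtracklayer::export(segments_to_granges(sim$segments),
                        file.path(dir, "segments.gff3"), format = "gff3")
  }
  write_fastq(sim$reads, file.path(dir, "reads.fastq"))
  if (!is.null(sim$events)) {
    readr::write_tsv(sim$events, file.path(dir, "truth_events.tsv"))
    readr::write_tsv(sim$junctions, file.path(dir, "truth_junctions.tsv"))
  }
  readr::write_tsv(select(sim$reads, -"seq"),
                   file.path(dir, "truth_reads.tsv"))
  invisible(dir)
}

#' Export per-segment J regions as GFF3
#'
#' @param j_regions Output of [delineate_all_j_regions()].
#' @param segments Segment annotation (for contig and genome offsets).
#' @param path Output GFF3 path.
#' @return `path`, invisibly.
#' @export
write_j_regions_gff <- function(j_regions, segments, path) {
  jr <- left_join(j_regions,
                  select(segments, "segment_id", "contig", "start"),
                  by = "segment_id")
  rows <- list()
  for (i in seq_len(nrow(jr))) {
    r <- jr[i, ]
    if (!is.na(r$j2_start)) {
      rows[[length(rows) + 1L]] <- tibble(
        contig = r$contig, start = r$start + r$j2_start - 1L,
        end = r$start + r$j2_end - 1L, type = "J2_region",
        ID = paste0(r$segment_id, "_J2_region"))
    }
    if (!is.na(r$j1_start)) {
      rows[[length(rows) + 1L]] <- tibble(
        contig = r$contig, start = r$start + r$j1_start - 1L,
        end = r$start + r$j1_end - 1L, type = "J1_region",
        ID = paste0(r$segment_id, "_J1_region"))
    }
  }
  df <- bind_rows(rows)
  gr <- GenomicRanges::GRanges(df$contig,
                               IRanges::IRanges(df$start, df$end), "+")
  S4Vectors::mcols(gr)$type <- df$type
  S4Vectors::mcols(gr)$ID <- df$ID
  rtracklayer::export(gr, path, format = "gff3")
  invisible(path)
}
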