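#' Histogram of junction positions along a circle
#'
#' Counts chimeric-read junction positions (circle coordinates, oriented
#' 5' DRJ to 3' DRJ) for one segment.
#'
#' @param chimeras Accepted, segment-assigned chimera tibble (see
#'   [assign_segments()]).
#' @param seg One-row segment annotation.
#' @return A tibble of class `junction_histogram` with `position`
#'   (1..circle length) and `count`; total count equals the number of
#'   chimeras on the segment.
#' @export
junction_histogram <- function(chimeras, seg) {
  stopifnot(nrow(seg) == 1)
  ch <- chimeras[!is.na(chimeras$segment_id) &
                   chimeras$segment_id == seg$segment_id, ]
  counts <- integer(seg$circle_length)
  pos <- ch$junction_on_circle
  pos <- pos[!is.na(pos) & pos >= 1 & pos <= seg$circle_length]
  if (length(pos)) {
    t <- table(pos)
    counts[as.integer(names(t))] <- as.integer(t)
  }
  structure(
    tibble(segment_id = seg$segment_id, position = seq_len(seg$circle_length),
           count = counts),
    class = c("junction_histogram", "tbl_df", "tbl", "data.frame"),
    him = c(seg$him_start_c, seg$him_end_c))
}

#' Delineate the empirical J1 and J2 regions inside a HIM
#'
#' The two junction hotspots inside the HIM are delineated the way the
#' study defines them: take the position supported by the most chimeric
#' reads, then extend to the surrounding positions until one is supported
#' by fewer than `min_support` reads. The procedure is applied twice (the
#' second mode is searched outside the first region); the two regions are
#' returned ordered along the circle as (J2, J1), since J2 precedes J1 in
#' the 5'DRJ-to-3'DRJ orientation. With a single mode, one region is
#' returned and the other is `NA` (soft failure).
#'
#' @param hist A [junction_histogram()] (or tibble with `position`/`count`).
#' @param him Integer length-2 vector: HIM interval in circle coordinates
#'   (defaults to the interval attached to the histogram).
#' @param min_support Minimum reads for a position to extend a region; the
#'   mode itself is always included.
#' @return A one-row tibble: `j2_start`, `j2_end`, `j1_start`, `j1_end`,
#'   `n_modes`, `gap` (bases strictly between the two regions).
#' @export
delineate_j_regions <- function(hist, him = NULL, min_support = 2) {
  him <- him %||% attr(hist, "him")
  stopifnot(length(him) == 2, !anyNA(him))
  x <- hist$count
  inside <- seq.int(him[1], him[2])
  grow <- function(mask, min_peak = 1L) {
    cand <- inside[mask[inside - him[1] + 1L]]
    if (!length(cand) || max(x[cand]) < min_peak) return(NULL)
    peak <- cand[which.max(x[cand])]
    ok <- function(pos) {
      pos >= him[1] && pos <= him[2] && mask[pos - him[1] + 1L] &&
        x[pos] >= min_support
    }
    lo <- peak
    while (ok(lo - 1L)) lo <- lo - 1L
    hi <- peak
    while (ok(hi + 1L)) hi <- hi + 1L
    c(lo, hi)
  }
  mask <- rep(TRUE, length(inside))
  r1 <- grow(mask)
  if (is.null(r1)) {
    return(tibble(j2_start = NA_integer_, j2_end = NA_integer_,
                  j1_start = NA_integer_, j1_end = NA_integer_,
                  n_modes = 0L, gap = NA_integer_))
  }
  mask[(r1[1]:r1[2]) - him[1] + 1L] <- FALSE
  # a second hotspot must itself clear the support threshold
  r2 <- grow(mask, min_peak = min_support)
  if (is.null(r2)) {
    return(tibble(j2_start = r1[1], j2_end = r1[2],
                  j1_start = NA_integer_, j1_end = NA_integer_,
                  n_modes = 1L, gap = NA_integer_))
  }
  regions <- if (r1[1] <= r2[1]) list(r1, r2) else list(r2, r1)
  tibble(j2_start = regions[[1]][1], j2_end = regions[[1]][2],
         j1_start = regions[[2]][1], j1_end = regions[[2]][2],
         n_modes = 2L,
         gap = regions[[2]][1] - regions[[1]][2] - 1L)
}

#' Delineate J regions for every HIM-bearing segment
#'
#' @param chimeras Accepted, segment-assigned chimeras.
#' @param segments Segment annotation.
#' @param min_support Passed to [delineate_j_regions()].
#' @return A tibble with one row per HIM-bearing segment.
#' @export
delineate_all_j_regions <- function(chimeras, segments, min_support = 2) {
  him_segs <- segments[segments$has_him, , drop = FALSE]
  bind_rows(lapply(seq_len(nrow(him_segs)), function(i) {
    seg <- him_segs[i, ]
    h <- junction_histogram(chimeras, seg)
    r <- delineate_j_regions(h, min_support = min_support)
    r$segment_id <- seg$segment_id
    r
  }))
}

#' Classify junctions into J1 / J2 / HIM-other / outside-HIM categories
#'
#' Each chimera is assigned exactly one category from the wasp-side junction
#' position on the circle: inside the J1 region, inside the J2 region,
#' inside the HIM but in neither J region, or outside the HIM (which
#' includes junctions on segments without a HIM and junctions outside any
#' segment). The categories partition the chimera set.
#'
#' @param chimeras Accepted, segment-assigned chimeras.
#' @param segments Segment annotation.
#' @param j_regions Per-segment J regions, either from
#'   [delineate_all_j_regions()] (empirical, the study's approach) or built
#'   from the annotated motif intervals via [annotated_j_regions()].
#' @return The chimera tibble with a `junction_class` factor column
#'   (`J1`, `J2`, `HIM_other`, `outside_HIM`).
#' @export
classify_junctions <- function(chimeras, segments, j_regions) {
  ch <- chimeras
  cls <- rep("outside_HIM", nrow(ch))
  seg_idx <- match(ch$segment_id, segments$segment_id)
  jr_idx <- match(ch$segment_id, j_regions$segment_id)
  pos <- ch$junction_on_circle
  in_him <- !is.na(seg_idx) & segments$has_him[seg_idx] &
    !is.na(pos) &
    pos >= segments$him_start_c[seg_idx] & pos <= segments$him_end_c[seg_idx]
  cls[in_him] <- "HIM_other"
  in_reg <- function(lo, hi) {
    !is.na(jr_idx) & !is.na(pos) & !is.na(lo) & !is.na(hi) &
      pos >= lo & pos <= hi & in_him
  }
  cls[in_reg(j_regions$j2_start[jr_idx], j_regions$j2_end[jr_idx])] <- "J2"
  cls[in_reg(j_regions$j1_start[jr_idx], j_regions$j1_end[jr_idx])] <- "J1"
  ch$junction_class <- factor(cls, levels = c("J1", "J2", "HIM_other",
                                              "outside_HIM"))
  ch
}

#' J regions taken from the simulator's motif annotation
#'
#' @param segments Segment annotation with `j1_*_c` / `j2_*_c` columns.
#' @return A tibble usable as `j_regions` in [classify_junctions()].
#' @export
annotated_j_regions <- function(segments) {
  him_segs <- segments[segments$has_him, , drop = FALSE]
  tibble(segment_id = him_segs$segment_id,
         j2_start = him_segs$j2_start_c, j2_end = him_segs$j2_end_c,
         j1_start = him_segs$j1_start_c, j1_end = him_segs$j1_end_c)
}

#' Per-segment junction category counts
#'
#' @param chimeras Output of [classify_junctions()].
#' @return A tibble of counts per segment and category (all categories
#'   present, zero-filled), whose total equals the number of chimeras.
#' @export
junction_category_counts <- function(chimeras) {
  chimeras |>
    mutate(segment_id = ifelse(is.na(.data$segment_id), "<none>",
                               .data$segment_id)) |>
    count(.data$segment_id, .data$junction_class, .drop = FALSE,
          name = "n_reads")
}
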