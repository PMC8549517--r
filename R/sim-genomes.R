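#' Generate toy wasp and host genomes with annotated proviral segments
#'
#' Plants `n_segments` non-overlapping proviral segments in a random wasp
#' genome. Each segment is flanked by two identical direct repeat junctions
#' (DRJs, one random sequence per segment) and a `him_fraction` of segments
#' carry a host integration motif (HIM) laid out as J2 + spacer + J1 near
#' the 3' DRJ, with the J motifs conserved across segments up to
#' `j_divergence`. Coordinates are 1-based inclusive; circle coordinates
#' count from the first base of the 5' DRJ (the copy retained on the excised
#' circle).
#'
#' @param config A [sim_config()].
#' @return A list with `host` and `wasp` (named character vectors of
#'   sequences) and `segments`, a tibble with one row per segment: genome
#'   coordinates of the segment, its DRJs, HIM and J motifs, plus
#'   circle-coordinate columns (`*_c`) and the canonical cut positions
#'   `cut2_c` (inside/at the J2-spacer boundary) and `cut1_c` (spacer-J1
#'   boundary) used for HIM-mediated integration.
#' @export
gen_genomes <- function(config) {
  validate_sim_config(config)
  with_seed(derive_seed(config$seed, "genomes"), gen_genomes_impl(config))
}

gen_genomes_impl <- function(cfg) {
  host <- c(host_1 = rand_dna(cfg$host_length, cfg$gc))
  n <- cfg$n_segments
  if (n == 0) {
    return(list(host = host,
                wasp = c(wasp_1 = rand_dna(cfg$wasp_length, cfg$gc)),
                segments = empty_segments()))
  }

  j2_canon <- rand_dna(cfg$j_length, cfg$gc)
  j1_canon <- rand_dna(cfg$j_length, cfg$gc)
  n_him <- round(cfg$him_fraction * n)
  has_him <- seq_len(n) %in% sample.int(n, n_him)

  body_len <- sample(cfg$segment_body[1]:cfg$segment_body[2], n, replace = TRUE)
  spacer_len <- sample(cfg$spacer_range[1]:cfg$spacer_range[2], n, replace = TRUE)
  right_body <- sample(150:300, n, replace = TRUE)
  him_len <- ifelse(has_him, 2L * cfg$j_length + spacer_len, 0L)
  seg_len <- 2L * cfg$drj_length + body_len + him_len

  min_gap <- 200L
  total <- sum(seg_len) + (n + 1L) * min_gap
  if (total > cfg$wasp_length) {
    abort(sprintf(
      "segments (%d bp incl. minimal gaps) do not fit in wasp_length = %d bp",
      total, cfg$wasp_length))
  }
  # distribute the slack randomly over the n + 1 gaps
  slack <- cfg$wasp_length - total
  cuts <- sort(sample.int(slack + 1L, n, replace = TRUE)) - 1L
  gap <- diff(c(0L, cuts, slack)) + min_gap

  segs <- vector("list", n)
  pieces <- character(2L * n + 1L)
  pos <- 1L
  for (i in seq_len(n)) {
    pieces[2L * i - 1L] <- rand_dna(gap[i], cfg$gc)
    pos <- pos + gap[i]
    drj <- rand_dna(cfg$drj_length, cfg$gc)
    if (has_him[i]) {
      n_mut <- round(cfg$j_divergence * cfg$j_length)
      j2 <- mutate_seq(j2_canon, n_mut)
      j1 <- mutate_seq(j1_canon, n_mut)
      left_body <- rand_dna(body_len[i] - right_body[i], cfg$gc)
      spacer <- rand_dna(spacer_len[i], cfg$gc)
      # keep the two cut sites sequence-distinguishable: the spacer must not
      # begin with the same bases as J1, or planted microhomology tracts
      # would silently recreate spacer homology and drift the J2-side
      # junction coordinate
      for (k in 1:2) {
        if (substr(spacer, k, k) == substr(j1, k, k)) {
          spacer <- replace_subseq(
            spacer, k, sample(setdiff(DNA_BASES, substr(j1, k, k)), 1))
        }
      }
      seq_i <- paste0(drj, left_body, j2, spacer, j1,
                      rand_dna(right_body[i], cfg$gc), drj)
      him_start <- pos + cfg$drj_length + nchar(left_body)
      j2_start <- him_start
      j2_end <- j2_start + cfg$j_length - 1L
      j1_start <- j2_end + spacer_len[i] + 1L
      j1_end <- j1_start + cfg$j_length - 1L
      him_end <- j1_end
    } else {
      seq_i <- paste0(drj, rand_dna(body_len[i], cfg$gc), drj)
      him_start <- j2_start <- j2_end <- j1_start <- j1_end <- him_end <- NA_integer_
    }
    seg_start <- pos
    seg_end <- pos + seg_len[i] - 1L
    hh <- has_him[i]
    spc <- if (hh) spacer_len[i] else NA_integer_
    segs[[i]] <- tibble(
      segment_id = sprintf("S%d", i),
      contig = "wasp_1",
      start = seg_start, end = seg_end,
      drj_length = cfg$drj_length,
      drj5_start = seg_start, drj5_end = seg_start + cfg$drj_length - 1L,
      drj3_start = seg_end - cfg$drj_length + 1L, drj3_end = seg_end,
      has_him = hh,
      him_start = him_start, him_end = him_end,
      j2_start = j2_start, j2_end = j2_end,
      j1_start = j1_start, j1_end = j1_end,
      spacer_length = spc,
      circle_length = seg_len[i] - cfg$drj_length
    )
    pieces[2L * i] <- seq_i
    pos <- pos + seg_len[i]
  }
  pieces[2L * n + 1L] <- rand_dna(gap[n + 1L], cfg$gc)
  wasp <- c(wasp_1 = paste(pieces, collapse = ""))
  stopifnot(nchar(wasp) == cfg$wasp_length)

  segments <- bind_rows(segs)
  # circle coordinates (1 = first base of the retained DRJ) and canonical cuts
  segments <- segments |>
    mutate(
      him_start_c = .data$him_start - .data$start + 1L,
      him_end_c = .data$him_end - .data$start + 1L,
      j2_start_c = .data$j2_start - .data$start + 1L,
      j2_end_c = .data$j2_end - .data$start + 1L,
      j1_start_c = .data$j1_start - .data$start + 1L,
      j1_end_c = .data$j1_end - .data$start + 1L,
      cut2_c = .data$j2_end_c + cfg$cut_offset_j2,
      cut1_c = .data$j1_start_c - 1L + cfg$cut_offset_j1
    )
  list(host = host, wasp = wasp, segments = segments)
}

empty_segments <- function() {
  tibble(
    segment_id = character(), contig = character(),
    start = integer(), end = integer(), drj_length = integer(),
    drj5_start = integer(), drj5_end = integer(),
    drj3_start = integer(), drj3_end = integer(),
    has_him = logical(),
    him_start = integer(), him_end = integer(),
    j2_start = integer(), j2_end = integer(),
    j1_start = integer(), j1_end = integer(),
    spacer_length = integer(), circle_length = integer(),
    him_start_c = integer(), him_end_c = integer(),
    j2_start_c = integer(), j2_end_c = integer(),
    j1_start_c = integer(), j1_end_c = integer(),
    cut2_c = integer(), cut1_c = integer()
  )
}

#' Excise a bracovirus circle from the wasp genome
#'
#' Circularisation recombines the two identical DRJs flanking a proviral
#' segment, so the excised circle carries a single DRJ copy. The circle is
#' reported linearised starting at the retained DRJ; its length is the
#' segment length minus one DRJ.
#'
#' @param wasp Wasp genome sequence (single character string or named vector
#'   containing the segment's contig).
#' @param seg One-row tibble (a row of the `segments` table from
#'   [gen_genomes()]).
#' @return The circle sequence as a character string.
#' @export
excise_circle <- function(wasp, seg) {
  stopifnot(nrow(seg) == 1)
  seqs <- if (is.null(names(wasp))) setNames(wasp, seg$contig) else wasp
  x <- seqs[[seg$contig]]
  if (is.na(seg$drj3_start) || is.na(seg$drj5_start)) {
    abort("segment lacks a DRJ annotation; cannot excise a circle")
  }
  drj5 <- substr(x, seg$drj5_start, seg$drj5_end)
  drj3 <- substr(x, seg$drj3_start, seg$drj3_end)
  if (!identical(drj5, drj3)) {
    abort(sprintf("DRJ copies of %s are not identical; annotation error",
                  seg$segment_id))
  }
  substr(x, seg$start, seg$end - seg$drj_length)
}

# Linearised insert produced by cutting the circle at the canonical positions
# inside/at the J1 and J2 boundaries: J1 ends up at the left extremity and J2
# at the right one; the spacer (between cut2_c and cut1_c) is lost.
him_insert <- function(circle, seg) {
  paste0(substr(circle, seg$cut1_c + 1L, nchar(circle)),
         substr(circle, 1L, seg$cut2_c))
}

#' Integrate a circle into the host genome through its HIM
#'
#' Cuts the circle at the canonical breakpoints inside J1 and J2 (losing the
#' spacer), inserts the linearised sequence after `position` on the host
#' contig, and adjusts the host target site so that exactly `mh_len` bases
#' are shared between the J1-side insert extremity and the flanking host
#' sequence (the host base immediately beyond the shared tract is forced to
#' mismatch, and the host base adjoining the J1-side cut on the wasp side is
#' forced to mismatch the circle, so the requested microhomology is exact).
#'
#' Alongside the event record, the realized junction geometry is computed
#' with a maximal-score ungapped extension (+2/-3), the same local-alignment
#' convention the downstream chimera classifier sees, so that the truth table
#' carries the exact junction coordinates the pipeline is expected to report:
#' the wasp-side coordinate is the alignment end on the circle regardless of
#' any overlap, and incidental homology at the J2-side junction shifts that
#' junction's coordinates just as it would in real data.
#'
#' @param host Named character vector of host contig sequences.
#' @param circle Circle sequence from [excise_circle()].
#' @param seg One-row segment annotation (must have a HIM).
#' @param position Host position after which the insert is placed (1-based).
#' @param orientation `"+"` (insert forward: J1 on the left) or `"-"`.
#' @param mh_len Requested J1-side junction microhomology length (>= 0).
#' @param host_contig Name of the host contig (default: first).
#' @param event_id Identifier stored in the truth tables.
#' @return A list with `host` (modified sequences), `event` (one-row truth
#'   tibble) and `junctions` (two-row realized junction tibble with columns
#'   `side`, `junction_wasp` in circle coordinates, `junction_host`, and the
#'   realized `overlap_len`).
#' @export
integrate_circle <- function(host, circle, seg, position, orientation = "+",
                             mh_len = 0L, host_contig = names(host)[1],
                             event_id = "E1") {
  res <- plant_integration(host, circle, seg, position, orientation, mh_len,
                           host_contig, event_id)
  x <- res$host[[host_contig]]
  res$host[[host_contig]] <- paste0(substr(x, 1L, position), res$insert,
                                    substr(x, position + 1L, nchar(x)))
  res
}

# Adjusts the host reference around the target site and computes the truth
# record, but does not perform the insertion itself: junction coordinates
# stay on the unmodified-length reference, which is what read alignments
# against the host reference report.
plant_integration <- function(host, circle, seg, position, orientation = "+",
                              mh_len = 0L, host_contig = names(host)[1],
                              event_id = "E1") {
  stopifnot(nrow(seg) == 1, mh_len >= 0)
  if (!isTRUE(seg$has_him)) {
    abort(sprintf("segment %s has no HIM; non-HIM integration is not simulated",
                  seg$segment_id))
  }
  x <- host[[host_contig]]
  L <- nchar(x)
  if (position < mh_len + 2L || position > L - mh_len - 2L) {
    abort("position too close to the contig end for the requested microhomology")
  }
  insert <- him_insert(circle, seg)
  ins_or <- if (orientation == "+") insert else revcomp(insert)

  cut1 <- seg$cut1_c
  cut2 <- seg$cut2_c
  p <- as.integer(position)
  mh <- as.integer(mh_len)

  # `avoid` rewrites host base `at` so it matches none of the given bases
  # (used to make the requested shared tract exact and to scrub chance
  # first-base homology at the other junction); bases already forced by the
  # planted tract are left alone.
  avoid <- function(x, at, bases) {
    if (substr(x, at, at) %in% bases) {
      x <- replace_subseq(x, at, sample(setdiff(DNA_BASES, bases), 1))
    }
    x
  }
  cseq <- function(i, j) chars(clip_sub(circle, i, j))
  cbase <- function(i) substr(circle, i, i)

  # The J2-side wasp-alignment extension reads the same host bases as the
  # planted J1-side tract: it runs exactly as far as the tract matches the
  # spacer prefix. When the whole tract matches (always true for mh = 0),
  # the first free host base past the tract must mismatch both the J1-side
  # continuation (capping the shared tract) and the spacer continuation
  # (stopping the J2-side junction from drifting).
  m_spacer <- match_run(chars(substr(insert, 1L, mh)),
                        cseq(cut2 + 1L, cut2 + mh))
  cap_bases <- substr(insert, mh + 1L, mh + 1L)
  if (m_spacer == mh) cap_bases <- c(cap_bases, cbase(cut2 + mh + 1L))

  if (orientation == "+") {
    # left junction is J1-side: host alignment may extend into the insert
    if (mh > 0) x <- replace_subseq(x, p + 1L, substr(insert, 1L, mh))
    x <- avoid(x, p + mh + 1L, cap_bases)
    # hostref[p] feeds the J1-side wasp extension and the J2-side host
    # extension
    x <- avoid(x, p, c(cbase(cut1), cbase(cut2)))
  } else {
    # right junction is J1-side: shared tract sits left of the insert's end
    if (mh > 0) {
      x <- replace_subseq(x, p - mh + 1L, revcomp(substr(insert, 1L, mh)))
    }
    x <- avoid(x, p - mh, unname(comp_map[cap_bases]))
    # hostref[p+1] feeds the J1-side wasp extension and the J2-side host
    # extension
    x <- avoid(x, p + 1L, unname(comp_map[c(cbase(cut1), cbase(cut2))]))
  }

  # realized junction geometry under the aligner's local-alignment
  # convention: maximal-score (possibly gapped) extensions past each cut.
  # Each ext_dp() call gets the read-side continuation `a` and the
  # subject-side continuation `b`; i (read bases) feeds the overlap the
  # classifier measures, j (subject bases) shifts the reported coordinate.
  K <- 30L
  host_fwd <- chars(clip_sub(x, p + 1L, p + K))          # host bases after p
  host_rev <- rev(chars(clip_sub(x, p - K + 1L, p)))     # host bases before p+1
  if (orientation == "+") {
    e_h_l <- ext_dp(cseq(cut1 + 1L, cut1 + K), host_fwd)
    e_w_l <- ext_dp(host_rev, rev(cseq(cut1 - K + 1L, cut1)))
    e_w_r <- ext_dp(host_fwd, cseq(cut2 + 1L, cut2 + K))
    e_h_r <- ext_dp(rev(cseq(cut2 - K + 1L, cut2)), host_rev)
    junc <- tibble(
      event_id = event_id,
      side = c("J1", "J2"),
      junction_wasp = c(cut1 + 1L - e_w_l[2], cut2 + e_w_r[2]),
      junction_host = c(p + e_h_l[2], p + 1L - e_h_r[2]),
      overlap_len = c(e_h_l[1] + e_w_l[1], e_w_r[1] + e_h_r[1]),
      ext_into_host = c(e_w_l[1], e_w_r[1]),
      ext_into_wasp = c(e_h_l[1], e_h_r[1])
    )
  } else {
    comp_fwd <- function(i, j) unname(comp_map[cseq(i, j)])
    e_h_l <- ext_dp(rev(comp_fwd(cut2 - K + 1L, cut2)), host_fwd)
    e_w_l <- ext_dp(host_rev, comp_fwd(cut2 + 1L, cut2 + K))
    e_h_r <- ext_dp(comp_fwd(cut1 + 1L, cut1 + K), host_rev)
    e_w_r <- ext_dp(host_fwd, rev(comp_fwd(cut1 - K + 1L, cut1)))
    junc <- tibble(
      event_id = event_id,
      side = c("J2", "J1"),
      junction_wasp = c(cut2 + e_w_l[2], cut1 + 1L - e_w_r[2]),
      junction_host = c(p + e_h_l[2], p + 1L - e_h_r[2]),
      overlap_len = c(e_h_l[1] + e_w_l[1], e_w_r[1] + e_h_r[1]),
      ext_into_host = c(e_w_l[1], e_w_r[1]),
      ext_into_wasp = c(e_h_l[1], e_h_r[1])
    )
  }
  junc$segment_id <- seg$segment_id
  junc$host_contig <- host_contig
  junc$orientation <- orientation

  host[[host_contig]] <- x

  event <- tibble(
    event_id = event_id,
    segment_id = seg$segment_id,
    host_contig = host_contig,
    host_position = p,
    orientation = orientation,
    microhomology_length = mh,
    inserted_length = nchar(insert),
    spacer_length = seg$spacer_length,
    circle_length = nchar(circle)
  )
  list(host = host, event = event, junctions = junc, insert = ins_or)
}
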