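#' Simulate a complete integration study with ground truth
#'
#' End-to-end synthetic dataset: generates the two genomes, excises one
#' circle per segment, plants `n_integrations_per_segment` HIM-mediated
#' integrations per HIM-bearing segment at well-separated host positions
#' with requested junction microhomologies, and simulates reads from four
#' compartments: host background, wasp background, excised circles
#' (abundance-weighted, emulating non-integrated circle load) and
#' junction-spanning fragments around every integration junction.
#'
#' The host reference returned is the *pre-integration* reference (with the
#' microhomology-planting base adjustments): truth coordinates live on it,
#' and junction reads are generated from per-event integrated alleles, the
#' way a fixed reference genome relates to somatically integrated cells.
#'
#' @param config A [sim_config()].
#' @return An object of class `him_sim`: a list with `config`, `host`,
#'   `wasp` (named sequence vectors), `segments`, `circles` (named character
#'   vector, `circle_<segment_id>`), `events` (truth events), `junctions`
#'   (realized per-junction truth: coordinates under the alignment-end
#'   convention and realized overlap splits) and `reads` (read-truth table).
#' @export
simulate_dataset <- function(config) {
  validate_sim_config(config)
  gen <- gen_genomes(config)
  segments <- gen$segments
  host <- gen$host
  wasp <- gen$wasp

  circles <- character(0)
  if (nrow(segments) > 0) {
    circles <- vapply(seq_len(nrow(segments)), function(i) {
      excise_circle(wasp, segments[i, ])
    }, character(1))
    names(circles) <- paste0("circle_", segments$segment_id)
  }

  him_segs <- segments[segments$has_him, , drop = FALSE]
  n_int <- if (nrow(him_segs) > 0) {
    rep_len(config$n_integrations_per_segment, nrow(him_segs))
  } else {
    integer(0)
  }

  events <- list(); junctions <- list(); inserts <- list()
  if (sum(n_int) > 0) {
    with_seed(derive_seed(config$seed, "events"), {
      total <- sum(n_int)
      spacing <- 2L * config$read_length + 40L
      lo <- spacing; hi <- config$host_length - spacing
      if ((hi - lo) < total * spacing) {
        abort("host_length too small for the requested number of integrations")
      }
      # positions on a jittered grid guarantee the minimum spacing
      slots <- seq(lo, hi - spacing, by = spacing)
      pos <- sort(sample(slots, total)) +
        sample.int(spacing - 2L * 20L, total, replace = TRUE)
      ori <- sample(c("+", "-"), total, replace = TRUE)
      mh_levels <- seq_along(config$microhomology_probs) - 1L
      mh <- sample(mh_levels, total, replace = TRUE,
                   prob = config$microhomology_probs)
      seg_idx <- rep(seq_len(nrow(him_segs)), n_int)
      for (k in seq_len(total)) {
        seg <- him_segs[seg_idx[k], ]
        res <- plant_integration(
          host, circles[[paste0("circle_", seg$segment_id)]], seg,
          position = pos[k], orientation = ori[k], mh_len = mh[k],
          host_contig = "host_1", event_id = sprintf("E%d", k))
        host <- res$host
        events[[k]] <- res$event
        junctions[[k]] <- res$junctions
        inserts[[k]] <- res$insert
      }
    })
  }
  events <- if (length(events)) bind_rows(events) else NULL
  junctions <- if (length(junctions)) {
    bind_rows(lapply(junctions, function(j) {
      j$flank <- c("left", "right"); j
    }))
  } else {
    NULL
  }

  reads <- with_seed(derive_seed(config$seed, "readgen"), {
    raw <- list()
    raw$host <- sample_reads_raw(host[["host_1"]], "host_1", "host_bg",
                                 config$depth_host, config$read_length)
    raw$wasp <- sample_reads_raw(wasp[["wasp_1"]], "wasp_1", "wasp_bg",
                                 config$depth_wasp, config$read_length)
    if (config$depth_circles > 0 && length(circles) > 0) {
      cn <- rep_len(config$segment_copy_number, length(circles))
      raw$circ <- bind_rows(lapply(seq_along(circles), function(i) {
        sample_reads_raw(circles[[i]], names(circles)[i], "circle",
                         config$depth_circles * cn[i], config$read_length)
      }))
    }
    if (!is.null(junctions) && config$depth_junction > 0) {
      raw$junc <- junction_reads_raw(host[["host_1"]], inserts, events,
                                     junctions, config)
    }
    reads <- bind_rows(raw)
    finish_reads(reads, config$read_length, config$error_rate,
                 config$pcr_dup_rate)
  })

  structure(list(config = config, host = host, wasp = wasp,
                 segments = segments, circles = circles,
                 events = events, junctions = junctions, reads = reads),
            class = "him_sim")
}

sample_reads_raw <- function(seq, name, type, depth, read_length) {
  len <- nchar(seq)
  n <- round(depth * len / read_length)
  if (n == 0) return(NULL)
  starts <- sample.int(len - read_length + 1L, n, replace = TRUE)
  tibble(read_id = sprintf("%s_%s_r%d", type, name, seq_len(n)),
         source_type = type, source = name,
         event_id = NA_character_, side = NA_character_,
         start = starts, end = starts + as.integer(read_length) - 1L,
         left_len = NA_integer_, right_len = NA_integer_,
         seq = substring(seq, starts, starts + read_length - 1L))
}

# Reads spanning each integration junction, drawn from the integrated-allele
# sequence; left_len/right_len give the bases falling on each side of the
# junction boundary.
junction_reads_raw <- function(hostref, inserts, events, junctions, cfg) {
  L <- cfg$read_length
  out <- vector("list", nrow(junctions))
  for (r in seq_len(nrow(junctions))) {
    j <- junctions[r, ]
    ev <- events[match(j$event_id, events$event_id), ]
    ins <- inserts[[match(j$event_id, events$event_id)]]
    p <- ev$host_position
    if (j$flank == "left") {
      W <- paste0(clip_sub(hostref, p - L + 1L, p), substr(ins, 1L, L))
    } else {
      W <- paste0(substr(ins, nchar(ins) - L + 1L, nchar(ins)),
                  clip_sub(hostref, p + 1L, p + L))
    }
    n <- rpois(1, cfg$depth_junction)
    if (n == 0) next
    s <- sample.int(L + 1L, n, replace = TRUE)
    out[[r]] <- tibble(
      read_id = sprintf("jn_%s_%s_r%d", j$event_id, j$side, seq_len(n)),
      source_type = "junction", source = j$event_id,
      event_id = j$event_id, side = j$side,
      start = s, end = s + L - 1L,
      left_len = L - s + 1L, right_len = s - 1L,
      seq = substring(W, s, s + L - 1L))
  }
  bind_rows(out)
}

#' Truth junctions recoverable by the chimera filters
#'
#' A junction counts as recoverable when at least one simulated read has at
#' least `min_side` bases aligning exclusively to each genome (its flank
#' length minus the realized overlap extension on that side) and the
#' realized overlap does not exceed `max_overlap`.
#'
#' @param sim A `him_sim` object.
#' @param min_side Minimum exclusive bases per genome (default 16).
#' @param max_overlap Maximum doubly-aligned bases (default 20).
#' @return The subset of `sim$junctions` that is recoverable, with a
#'   `n_informative_reads` column.
#' @export
recoverable_junctions <- function(sim, min_side = 16, max_overlap = 20) {
  jr <- sim$reads[sim$reads$source_type == "junction" & !sim$reads$is_dup, ]
  jr <- left_join(jr,
                  select(sim$junctions, "event_id", "side",
                         "ext_into_host", "ext_into_wasp", "flank"),
                  by = c("event_id", "side"))
  # host side is the left flank at a "left" junction, the right flank otherwise
  host_len <- ifelse(jr$flank == "left", jr$left_len, jr$right_len)
  wasp_len <- ifelse(jr$flank == "left", jr$right_len, jr$left_len)
  ok <- (host_len - jr$ext_into_host) >= min_side &
    (wasp_len - jr$ext_into_wasp) >= min_side
  counts <- jr[ok, ] |>
    count(.data$event_id, .data$side, name = "n_informative_reads")
  out <- dplyr::inner_join(sim$junctions, counts, by = c("event_id", "side"))
  out[out$overlap_len <= max_overlap, , drop = FALSE]
}

#' @export
print.him_sim <- function(x, ...) {
  cat("<him_sim>\n")
  cat(sprintf("  wasp %s bp (%d segments), host %s bp\n",
              format(nchar(x$wasp[[1]]), big.mark = ","),
              nrow(x$segments),
              format(nchar(x$host[[1]]), big.mark = ",")))
  cat(sprintf("  %d integration events (%d junctions), %d reads\n",
              if (is.null(x$events)) 0L else nrow(x$events),
              if (is.null(x$junctions)) 0L else nrow(x$junctions),
              nrow(x$reads)))
  invisible(x)
}
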