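# Build a small wasp-like genome holding an intact proviral segment, an
# integrated-circle duplication (Hdp: J1 ... body+internal DRJ ... J2, no
# terminal DRJs) and a rearranged duplication (Rdp: body with one internal
# DRJ, no flanking DRJ or J motifs). All sequences are generated in code.
make_dup_genome <- function(seed = 202) {
  set.seed(seed)
  drj <- himera:::rand_dna(80)
  j2 <- himera:::rand_dna(30)
  j1 <- himera:::rand_dna(30)
  spacer <- himera:::rand_dna(55)
  him <- paste0(j2, spacer, j1)
  body_l <- himera:::rand_dna(700)
  body_r <- himera:::rand_dna(250)
  intact <- paste0(drj, body_l, him, body_r, drj)

  # integrated-circle copy: J1-side first, internal retained DRJ, J2 last
  hdp <- paste0(j1, body_r, drj, body_l, j2)
  rdp_body <- himera:::rand_dna(500)
  rdp <- paste0(rdp_body, drj, himera:::rand_dna(420))

  gap <- function() himera:::rand_dna(400)
  genome_seq <- paste0(gap(), intact, gap(), hdp, gap(), rdp, gap())
  list(
    genome = c(contig_1 = genome_seq),
    motifs = list(him = c(HIM_S1 = him), drj = c(DRJ_S1 = drj),
                  segment = c(SEG_RDP = rdp)),
    boundary = tibble::tibble(motif_id = "HIM_S1", j2_end = nchar(j2),
                              j1_start = nchar(j2) + nchar(spacer) + 1L),
    coords = list(intact_start = 401,
                  hdp_start = 401 + nchar(intact) + 400,
                  hdp_len = nchar(hdp),
                  rdp_start = 401 + nchar(intact) + 400 + nchar(hdp) + 400,
                  rdp_len = nchar(rdp))
  )
}

test_that("search_motifs finds planted motifs on both strands", {
  g <- make_dup_genome()
  hits <- search_motifs(g$genome, g$motifs$him)
  full <- hits[hits$motif_end - hits$motif_start + 1 == nchar(g$motifs$him), ]
  expect_gte(nrow(full), 1)
  expect_equal(full$start[1], g$coords$intact_start + 80 + 700)
  expect_equal(full$strand[1], "+")

  # absent motif: empty result
  none <- search_motifs(g$genome, c(missing = himera:::rand_dna(60)))
  expect_equal(nrow(none), 0)

  # reverse-strand planting is reported on forward coordinates, minus strand
  rc <- c(contig_1 = himera:::revcomp(g$genome[[1]]))
  hits_rc <- search_motifs(rc, g$motifs$him)
  full_rc <- hits_rc[hits_rc$motif_end - hits_rc$motif_start + 1 ==
                       nchar(g$motifs$him), ]
  expect_true(all(full_rc$strand == "-"))
  expect_true(all(full_rc$start <= full_rc$end))

  expect_error(search_motifs(c(x = ""), g$motifs$him), "empty")
  expect_error(search_motifs(g$genome, character(0)), "empty")
})

test_that("planted Hdp and Rdp copies are called; intact segments are not", {
  g <- make_dup_genome()
  him_hits <- search_motifs(g$genome, g$motifs$him)
  drj_hits <- search_motifs(g$genome, g$motifs$drj)
  seg_hits <- search_motifs(g$genome, g$motifs$segment)
  bnd <- g$boundary

  calls <- call_him_duplications(him_hits, drj_hits = drj_hits,
                                 segment_hits = seg_hits,
                                 him_boundaries = bnd)
  expect_equal(sort(unique(calls$kind)), c("Hdp", "Rdp"))

  hdp <- calls[calls$kind == "Hdp", ]
  expect_equal(nrow(hdp), 1)
  expect_lt(abs(hdp$start - g$coords$hdp_start), 11)
  expect_lt(abs(hdp$end - (g$coords$hdp_start + g$coords$hdp_len - 1)), 11)
  expect_equal(hdp$parent_segment_id, "S1")

  rdp <- calls[calls$kind == "Rdp", ]
  expect_equal(nrow(rdp), 1)
  expect_lt(abs(rdp$start - g$coords$rdp_start), 40)

  # no call ever covers the intact segment's interior
  intact_mid <- g$coords$intact_start + 500
  expect_false(any(calls$start <= intact_mid & calls$end >= intact_mid &
                     calls$start <= g$coords$intact_start + 10))
})

test_that("duplication calls survive reverse-complementing the genome", {
  g <- make_dup_genome()
  L <- nchar(g$genome[[1]])
  rc <- c(contig_1 = himera:::revcomp(g$genome[[1]]))
  calls_fwd <- call_him_duplications(
    search_motifs(g$genome, g$motifs$him),
    drj_hits = search_motifs(g$genome, g$motifs$drj),
    segment_hits = search_motifs(g$genome, g$motifs$segment),
    him_boundaries = g$boundary)
  calls_rc <- call_him_duplications(
    search_motifs(rc, g$motifs$him),
    drj_hits = search_motifs(rc, g$motifs$drj),
    segment_hits = search_motifs(rc, g$motifs$segment),
    him_boundaries = g$boundary)
  expect_equal(nrow(calls_rc), nrow(calls_fwd))
  expect_equal(sort(calls_rc$kind), sort(calls_fwd$kind))
  # coordinates remap consistently under the strand flip
  hdp_f <- calls_fwd[calls_fwd$kind == "Hdp", ]
  hdp_r <- calls_rc[calls_rc$kind == "Hdp", ]
  expect_lt(abs((L - hdp_r$end + 1) - hdp_f$start), 11)

  # empty input, empty output
  none <- call_him_duplications(calls_fwd[0, c()] |>
                                  (\(x) search_motifs(g$genome,
                                                      g$motifs$him)[0, ])(),
                                drj_hits = search_motifs(g$genome,
                                                         g$motifs$drj)[0, ],
                                him_boundaries = g$boundary)
  expect_equal(nrow(none), 0)
})

test_that("genomes with only intact segments yield no duplication calls", {
  sim <- small_sim()
  seg <- sim$segments[1, ]
  wasp <- sim$wasp
  him <- substr(wasp[[1]], seg$him_start, seg$him_end)
  drj <- substr(wasp[[1]], seg$drj5_start, seg$drj5_end)
  him_hits <- search_motifs(wasp, c(HIM_S1 = him))
  drj_hits <- search_motifs(wasp, c(DRJ_S1 = drj))
  calls <- call_him_duplications(
    him_hits, drj_hits = drj_hits,
    him_boundaries = tibble::tibble(
      motif_id = "HIM_S1", j2_end = 30L,
      j1_start = 30L + seg$spacer_length + 1L))
  expect_equal(nrow(calls), 0)
})
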