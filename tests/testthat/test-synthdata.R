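test_that("gen_genomes plants the requested segment architecture", {
  cfg <- sim_config(host_length = 5e4, wasp_length = 6e4, n_segments = 16,
                    him_fraction = 1, seed = 3)
  g <- gen_genomes(cfg)
  segs <- g$segments

  expect_equal(nrow(segs), 16)
  expect_true(all(segs$has_him))
  expect_equal(nchar(g$wasp[[1]]), 6e4)
  expect_equal(nchar(g$host[[1]]), 5e4)

  # segments do not overlap
  expect_true(all(head(segs$end, -1) < tail(segs$start, -1)))

  # both DRJ copies are identical, and spacers sit in the canonical range
  wasp <- g$wasp[[1]]
  for (i in seq_len(nrow(segs))) {
    s <- segs[i, ]
    expect_identical(substr(wasp, s$drj5_start, s$drj5_end),
                     substr(wasp, s$drj3_start, s$drj3_end))
  }
  expect_true(all(segs$spacer_length >= 41 & segs$spacer_length <= 73))
  # HIM layout: J2 then spacer then J1 (5'DRJ -> 3'DRJ orientation)
  expect_true(all(segs$j2_end < segs$j1_start))
  expect_equal(segs$j1_start - segs$j2_end - 1L, segs$spacer_length)
})

test_that("gen_genomes handles the empty case and is deterministic", {
  cfg0 <- sim_config(n_segments = 0, host_length = 1e4, wasp_length = 1e4,
                     seed = 5)
  g0 <- gen_genomes(cfg0)
  expect_equal(nrow(g0$segments), 0)
  expect_equal(nchar(g0$wasp[[1]]), 1e4)

  cfg <- sim_config(host_length = 2e4, wasp_length = 3e4, n_segments = 3,
                    seed = 11)
  expect_identical(gen_genomes(cfg), gen_genomes(cfg))

  too_small <- sim_config(host_length = 1e4, wasp_length = 8e3,
                          n_segments = 4, seed = 1)
  expect_error(gen_genomes(too_small), "fit")
})

test_that("excise_circle collapses the two DRJs into one", {
  sim <- small_sim()
  seg <- sim$segments[1, ]
  circle <- excise_circle(sim$wasp, seg)

  expect_equal(nchar(circle), seg$end - seg$start + 1 - seg$drj_length)
  # exactly one copy of the DRJ remains on the circle
  drj <- substr(sim$wasp[[1]], seg$drj5_start, seg$drj5_end)
  hits <- gregexpr(drj, circle, fixed = TRUE)[[1]]
  expect_equal(length(hits[hits > 0]), 1)
  expect_equal(as.integer(hits[1]), 1)  # linearised from the retained DRJ

  # unmatched DRJs are an annotation error
  bad <- seg
  wasp_bad <- sim$wasp
  wasp_bad[[1]] <- paste0(substr(wasp_bad[[1]], 1, seg$drj3_start - 1),
                          "NNNN",
                          substr(wasp_bad[[1]], seg$drj3_start + 4,
                                 nchar(wasp_bad[[1]])))
  expect_error(excise_circle(wasp_bad, bad), "identical")
  bad$drj3_start <- NA_integer_
  expect_error(excise_circle(sim$wasp, bad), "DRJ")
})

test_that("integrate_circle removes the spacer and plants exact microhomology", {
  sim <- small_sim()
  wasp <- sim$wasp
  host <- sim$host
  for (orient in c("+", "-")) {
    for (mh in c(0L, 2L, 5L)) {
      seg <- sim$segments[2, ]
      circle <- excise_circle(wasp, seg)
      res <- integrate_circle(host, circle, seg, position = 30000,
                              orientation = orient, mh_len = mh,
                              event_id = sprintf("T_%s_%d", orient, mh))
      ev <- res$event
      expect_equal(ev$inserted_length, nchar(circle) - seg$spacer_length)
      expect_equal(nchar(res$host[[1]]), nchar(host[[1]]) + ev$inserted_length)
      # requested J1-side shared tract is exact on the reference: mh bases
      # match the insert extremity, the next one deliberately mismatches
      ref <- himera:::plant_integration(host, circle, seg, position = 30000,
                                        orientation = orient,
                                        mh_len = mh)$host[[1]]
      insert <- himera:::him_insert(circle, seg)
      p <- 30000
      if (orient == "+") {
        if (mh > 0) {
          expect_identical(substr(ref, p + 1, p + mh),
                           substr(insert, 1, mh))
        }
        expect_false(substr(ref, p + mh + 1, p + mh + 1) ==
                       substr(insert, mh + 1, mh + 1))
      } else {
        tail_mh <- himera:::revcomp(substr(insert, 1, mh))
        if (mh > 0) {
          expect_identical(substr(ref, p - mh + 1, p), tail_mh)
        }
        expect_false(substr(ref, p - mh, p - mh) ==
                       himera:::comp_map[[substr(insert, mh + 1, mh + 1)]])
      }
    }
  }
  seg_no_him <- sim$segments[1, ]
  seg_no_him$has_him <- FALSE
  circle <- excise_circle(wasp, sim$segments[1, ])
  expect_error(integrate_circle(host, circle, seg_no_him, 30000),
               "HIM")
})

test_that("simulate_reads hits target depth, error and duplicate settings", {
  src <- tibble::tibble(name = "chrA", seq = strrep("ACGT", 25000),
                        depth = 10)
  reads <- simulate_reads(src, read_length = 150, seed = 9)
  expect_equal(nrow(reads), round(10 * 1e5 / 150))  # ~6,667

  # pcr_dup_rate = 0: all identifiers unique
  expect_equal(anyDuplicated(reads$read_id), 0)

  # error_rate = 0: every plus-strand read is an exact substring
  plus <- reads[reads$strand == "+", ][1:50, ]
  expect_true(all(substring(src$seq, plus$start, plus$end) == plus$seq))

  dup <- simulate_reads(src, read_length = 150, pcr_dup_rate = 0.1,
                        seed = 9)
  expect_equal(sum(dup$is_dup), floor(0.1 * round(10 * 1e5 / 150)))

  expect_error(simulate_reads(tibble::tibble(name = "x", seq = "ACGT",
                                             depth = 5),
                              read_length = 150), "read_length")
})

test_that("realized mean depth is within 5% of target on a 100-kb source", {
  src <- tibble::tibble(name = "chr", seq = strrep("GATTACA", 15000),
                        depth = 20)
  reads <- simulate_reads(src, read_length = 150, seed = 21)
  track <- depth_track_from_reads(reads, "chr", nchar(src$seq))
  mean_depth <- sum((track$end - track$start) * track$depth) / nchar(src$seq)
  expect_lt(abs(mean_depth - 20) / 20, 0.05)
})

test_that("every simulated event satisfies the length bookkeeping", {
  sim <- small_sim()
  expect_true(all(sim$events$inserted_length + sim$events$spacer_length ==
                    sim$events$circle_length))
  expect_true(all(sim$junctions$overlap_len >= 0))
  # two junctions per event, J1 and J2 once each
  counts <- table(sim$junctions$event_id, sim$junctions$side)
  expect_true(all(counts == 1))
  # same seed gives byte-identical datasets
  sim2 <- simulate_dataset(sim$config)
  expect_identical(sim$reads$seq, sim2$reads$seq)
  expect_identical(sim$host, sim2$host)
})
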