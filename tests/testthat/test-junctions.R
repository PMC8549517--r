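fake_chimeras <- function(segment_id, positions) {
  tibble::tibble(read_id = sprintf("r%d", seq_along(positions)),
                 segment_id = segment_id, junction_on_circle = positions,
                 junction_on_host = 1000L + seq_along(positions),
                 host_subject_id = "host_1", orientation = "+",
                 host_flank = "left")
}

test_that("junction_histogram counts junctions along the circle", {
  sim <- small_sim()
  seg <- sim$segments[1, ]
  ch <- fake_chimeras(seg$segment_id, rep(seg$j1_start_c, 5))
  h <- junction_histogram(ch, seg)
  expect_equal(sum(h$count), 5)
  expect_equal(h$count[h$position == seg$j1_start_c], 5)

  h0 <- junction_histogram(ch[0, ], seg)
  expect_true(all(h0$count == 0))
  expect_equal(nrow(h0), seg$circle_length)
})

test_that("J regions grow from the mode until support drops below 2", {
  hist <- tibble::tibble(position = 1:200, count = 0L)
  p <- 100L
  hist$count[(p - 3):(p + 3)] <- c(0L, 1L, 3L, 7L, 3L, 1L, 0L)
  r <- delineate_j_regions(hist, him = c(50L, 150L))
  expect_equal(r$n_modes, 1)
  expect_equal(c(r$j2_start, r$j2_end), c(p - 1L, p + 1L))

  # two modes separated by a spacer-sized run of zeros give two regions
  hist2 <- tibble::tibble(position = 1:300, count = 0L)
  hist2$count[100:101] <- c(9L, 2L)
  hist2$count[160:161] <- c(3L, 8L)
  r2 <- delineate_j_regions(hist2, him = c(80L, 200L))
  expect_equal(r2$n_modes, 2)
  expect_equal(c(r2$j2_start, r2$j2_end), c(100L, 101L))
  expect_equal(c(r2$j1_start, r2$j1_end), c(160L, 161L))
  expect_equal(r2$gap, 58L)

  # a lone supporting read still anchors a width-zero region at the mode
  hist3 <- tibble::tibble(position = 1:100, count = 0L)
  hist3$count[40] <- 1L
  r3 <- delineate_j_regions(hist3, him = c(20L, 80L))
  expect_equal(c(r3$j2_start, r3$j2_end), c(40L, 40L))
  expect_equal(r3$n_modes, 1)

  # nothing inside the HIM: soft no-region result
  r4 <- delineate_j_regions(tibble::tibble(position = 1:50, count = 0L),
                            him = c(10L, 40L))
  expect_equal(r4$n_modes, 0)
})

test_that("junction categories partition the chimera set", {
  sim <- small_sim()
  seg <- sim$segments
  s1 <- seg[1, ]
  jr <- annotated_j_regions(seg)
  ch <- fake_chimeras(s1$segment_id, c(
    s1$j1_start_c,              # J1
    s1$j2_end_c,                # J2
    s1$j2_end_c + 2L,           # inside HIM, outside both J regions
    s1$him_start_c - 50L,       # in segment, outside HIM
    NA))                        # outside any segment
  ch$segment_id[5] <- NA_character_
  out <- classify_junctions(ch, seg, jr)
  expect_equal(as.character(out$junction_class),
               c("J1", "J2", "HIM_other", "outside_HIM", "outside_HIM"))
  expect_equal(sum(table(out$junction_class)), nrow(ch))
})

test_that("empirically delineated regions recover the planted cuts", {
  rep <- study_report()
  sim <- rep$sim
  segs <- sim$segments
  jr <- rep$j_regions
  for (i in seq_len(nrow(segs))) {
    s <- segs[i, ]
    r <- jr[jr$segment_id == s$segment_id, ]
    expect_equal(r$n_modes, 2)
    # true cut positions (J2-side and J1-side junction coordinates)
    expect_true(r$j2_start <= s$cut2_c && s$cut2_c <= r$j2_end)
    expect_true(r$j1_start <= s$cut1_c + 1L && s$cut1_c + 1L <= r$j1_end)
    expect_lte(abs(r$gap - s$spacer_length), 2)
  }
})

test_that("junction mass concentrates inside HIMs on HIM-only simulations", {
  rep <- study_report()
  counts <- junction_category_counts(rep$chimeras)
  by_seg <- tidyr::pivot_wider(counts, names_from = "junction_class",
                               values_from = "n_reads")
  frac_him <- (by_seg$J1 + by_seg$J2 + by_seg$HIM_other) /
    (by_seg$J1 + by_seg$J2 + by_seg$HIM_other + by_seg$outside_HIM)
  expect_true(all(frac_him >= 0.875))
})
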