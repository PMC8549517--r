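aln_row <- function(read_id = "r1", subject_id = "s1", pident = 100,
                    len = 50, mm = 0, gaps = 0, qs = 1, qe = 50,
                    ss = 1000, se = 1049, ev = 1e-20, bs = 100) {
  tibble::tibble(read_id = read_id, subject_id = subject_id,
                 percent_identity = pident, align_length = len,
                 mismatches = mm, gap_opens = gaps,
                 read_start = qs, read_end = qe,
                 sbj_start = ss, sbj_end = se, evalue = ev, bitscore = bs)
}

write_aln <- function(rows, path = tempfile(fileext = ".tsv")) {
  readr::write_tsv(rows, path, col_names = FALSE)
  path
}

test_that("parse_alignment_table reads and normalises the 12-column dialect", {
  rows <- dplyr::bind_rows(
    aln_row("r1"), aln_row("r2", ss = 2000, se = 1951),
    aln_row("r3", qs = 50, qe = 1, ss = 300, se = 349))  # minus-on-read dialect
  p <- write_aln(rows)
  hits <- parse_alignment_table(p)
  expect_equal(nrow(hits), 3)
  expect_true(all(hits$read_start <= hits$read_end))
  r3 <- hits[hits$read_id == "r3", ]
  expect_equal(c(r3$read_start, r3$read_end), c(1, 50))
  expect_equal(c(r3$sbj_start, r3$sbj_end), c(349, 300))
  expect_equal(r3$strand, "-")
  expect_equal(hits$strand[hits$read_id == "r2"], "-")

  empty <- tempfile(); file.create(empty)
  expect_equal(nrow(parse_alignment_table(empty)), 0)

  bad <- tempfile()
  writeLines(c(paste(c("r1","s1",100,50,0,0,1,50,1,50,0,99), collapse = "\t"),
               "garbage\trow"), bad)
  expect_warning(h <- parse_alignment_table(bad), "malformed|missing")
  expect_equal(nrow(h), 1)

  expect_error(parse_alignment_table(tempfile()), "not found")
})

test_that("select_best_hit is deterministic under ties", {
  hits <- dplyr::bind_rows(
    aln_row("r1", bs = 100), aln_row("r1", bs = 90, ss = 5000, se = 5049),
    aln_row("r2", bs = 50, ss = 900, se = 949),
    aln_row("r2", bs = 50, ss = 500, se = 549))
  best <- select_best_hit(hits)
  expect_equal(nrow(best), 2)
  expect_equal(best$bitscore[best$read_id == "r1"], 100)
  expect_equal(best$sbj_start[best$read_id == "r2"], 500)
  expect_equal(nrow(select_best_hit(hits[0, ])), 0)
})

test_that("the four chimera filters behave as specified on 150-bp reads", {
  w <- function(qs, qe) aln_row("r", "wasp_1", qs = qs, qe = qe,
                                ss = 1000 + qs, se = 1000 + qe)
  h <- function(qs, qe) aln_row("r", "host_1", qs = qs, qe = qe,
                                ss = 5000 + qs, se = 5000 + qe)

  ok <- classify_chimera(150, w(1, 80), h(76, 150))
  expect_true(ok$accepted)
  expect_equal(ok$overlap_len, 5)
  expect_equal(ok$insert_len, 0)

  # (i) fewer than 16 wasp-exclusive bases
  r <- classify_chimera(150, w(1, 15), h(16, 150))
  expect_false(r$accepted); expect_equal(r$reason, "min_side_wasp")

  # (iii) more than 20 doubly-aligned bases
  r <- classify_chimera(150, w(1, 70), h(50, 150))
  expect_false(r$accepted); expect_equal(r$reason, "max_overlap")
  expect_equal(r$overlap_len, 21)

  # (iv) more than 5 inserted bases
  r <- classify_chimera(150, w(1, 70), h(77, 150))
  expect_false(r$accepted); expect_equal(r$reason, "max_insert")
  expect_equal(r$insert_len, 6)

  # (ii) 16 bases mapping to neither genome reach the strict 10% bound
  r <- classify_chimera(150, w(1, 64), h(81, 150))
  expect_false(r$accepted); expect_equal(r$reason, "unaligned")
  expect_equal(r$unaligned + r$insert_len, 16)

  # boundary: exactly 14 neither-genome bases pass the strict filter
  r <- classify_chimera(150, w(15, 80), h(76, 150))
  expect_true(r$accepted)
  expect_equal(r$unaligned, 14)

  expect_error(classify_chimera(150, aln_row("a"), aln_row("b")),
               "different reads")
})

test_that("base accounting partitions the read exactly (property)", {
  set.seed(77)
  for (i in 1:300) {
    L <- 150L
    ws <- sample.int(60, 1); we <- ws + sample.int(90, 1)
    hs <- sample.int(140, 1); he <- min(150L, hs + sample.int(90, 1))
    cls <- classify_chimera(
      L, aln_row("r", "w", qs = ws, qe = min(we, 150L), ss = 100 + ws,
                 se = 100 + min(we, 150L)),
      aln_row("r", "h", qs = hs, qe = he, ss = 900 + hs, se = 900 + he))
    expect_equal(cls$wasp_only + cls$host_only + cls$overlap_len +
                   cls$insert_len + cls$unaligned, L)
  }
})

test_that("junction coordinates follow the alignment-end convention", {
  # wasp left of host on the read, both plus strand: junction on wasp is
  # the wasp subject end, on host the host subject start, regardless of
  # the 5-bp overlap
  cls <- classify_chimera(
    150,
    aln_row("r", "wasp_1", qs = 1, qe = 80, ss = 2001, se = 2080),
    aln_row("r", "host_1", qs = 76, qe = 150, ss = 7076, se = 7150))
  expect_equal(cls$junction_on_wasp, 2080)
  expect_equal(cls$junction_on_host, 7076)
  expect_equal(cls$orientation, "+")
  expect_equal(cls$host_flank, "right")

  # host on the left, host hit on the minus strand
  cls2 <- classify_chimera(
    150,
    aln_row("r", "wasp_1", qs = 70, qe = 150, ss = 2001, se = 2081),
    aln_row("r", "host_1", qs = 1, qe = 72, ss = 7072, se = 7001))
  expect_equal(cls2$junction_on_wasp, 2001)
  expect_equal(cls2$junction_on_host, 7001)
  expect_equal(cls2$orientation, "-")
  expect_equal(cls2$host_flank, "right")
})

test_that("PCR deduplication collapses identical fragments only", {
  base <- classify_chimera(
    150,
    aln_row("r1", "wasp_1", qs = 1, qe = 80, ss = 2001, se = 2080),
    aln_row("r1", "host_1", qs = 76, qe = 150, ss = 7076, se = 7150))
  dup <- base; dup$read_id <- "r1_dup"
  other <- classify_chimera(
    150,
    aln_row("r2", "wasp_1", qs = 5, qe = 80, ss = 2005, se = 2080),
    aln_row("r2", "host_1", qs = 76, qe = 150, ss = 7076, se = 7150))
  all3 <- dplyr::bind_rows(base, dup, other)

  out <- dedupe_pcr(all3)
  expect_equal(nrow(out), 2)  # same junction, different boundaries: kept
  expect_equal(attr(out, "n_removed"), 1)

  # idempotent
  out2 <- dedupe_pcr(out)
  expect_equal(nrow(out2), 2)
  expect_equal(attr(out2, "n_removed"), 0)

  e <- dedupe_pcr(all3[0, ])
  expect_equal(nrow(e), 0)
})

test_that("reads outside annotated segments are flagged, not dropped", {
  sim <- small_sim()
  seg <- sim$segments
  ch <- classify_chimera(
    150,
    aln_row("r1", "wasp_1", qs = 1, qe = 80, ss = seg$start[1] + 200,
            se = seg$start[1] + 279),
    aln_row("r1", "host_1", qs = 81, qe = 150, ss = 7081, se = 7150))
  ch2 <- classify_chimera(
    150,
    aln_row("r2", "wasp_1", qs = 1, qe = 80, ss = 10, se = 89),
    aln_row("r2", "host_1", qs = 81, qe = 150, ss = 7081, se = 7150))
  out <- assign_segments(dplyr::bind_rows(ch, ch2), seg)
  expect_equal(out$segment_id[out$read_id == "r1"], seg$segment_id[1])
  expect_true(out$in_segment[out$read_id == "r1"])
  expect_false(out$in_segment[out$read_id == "r2"])
  expect_equal(nrow(out), 2)

  # a wasp coordinate in the 3' DRJ wraps onto the retained circle DRJ
  s1 <- seg[1, ]
  ch3 <- assign_segments(classify_chimera(
    150,
    aln_row("r3", "wasp_1", qs = 1, qe = 80, ss = s1$drj3_start + 4,
            se = s1$drj3_start + 83),
    aln_row("r3", "host_1", qs = 81, qe = 150, ss = 7081, se = 7150)), seg)
  expect_equal(ch3$junction_on_circle, 5 + 79)
})
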