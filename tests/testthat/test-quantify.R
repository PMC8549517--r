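test_that("normalisation formulas match their worked examples", {
  expect_equal(ipmh(100, 5e7), 2)
  expect_equal(ipmh(0, 1e6), 0)
  expect_equal(ipmh(625, 5e7), 12.5)
  expect_error(ipmh(10, 0), "positive")

  expect_equal(round(ies_per_genome(12.5, 150, 1021), 2), 85.08)
  expect_equal(ies_per_genome(150, 150, 1), 1)
  expect_equal(ies_per_genome(0, 150, 1021), 0)

  # scaling properties: joint scaling cancels; single-factor scaling is
  # linear (events) or inverse (mapped reads)
  set.seed(1)
  for (i in 1:20) {
    n <- sample.int(5000, 1); m <- sample.int(1e8, 1); k <- runif(1, 0.1, 9)
    expect_equal(ipmh(k * n, k * m), ipmh(n, m))
    expect_equal(ipmh(k * n, m), k * ipmh(n, m))
    expect_equal(ipmh(n, k * m), ipmh(n, m) / k)
  }

  expect_equal(max_cells_sequenced(155), 77)
  expect_equal(max_cells_sequenced(70), 35)
})

test_that("call_ies groups unique junctions and sums support", {
  ch <- tibble::tibble(
    read_id = sprintf("r%d", 1:3),
    segment_id = "S1",
    junction_class = factor("J1", levels = c("J1", "J2", "HIM_other",
                                             "outside_HIM")),
    host_subject_id = "host_1",
    junction_on_host = c(100L, 200L, 300L),
    junction_on_circle = 50L,
    orientation = "+", host_flank = "left")
  ev <- call_ies(ch)
  expect_equal(nrow(ev), 3)
  expect_true(all(ev$support == 1))

  ch2 <- ch
  ch2$junction_on_host <- c(100L, 100L, 300L)
  ev2 <- call_ies(ch2)
  expect_equal(nrow(ev2), 2)
  expect_equal(sort(ev2$support), c(1L, 2L))
  # support adds up to the number of J1/J2 chimeras
  expect_equal(sum(ev2$support), 3)

  expect_equal(nrow(call_ies(ch[0, ])), 0)

  # junctions outside the J regions are excluded by default but kept with
  # a wider scope
  ch3 <- ch
  ch3$junction_class[2] <- "HIM_other"
  expect_equal(nrow(call_ies(ch3, scope = "j")), 2)
  expect_equal(nrow(call_ies(ch3, scope = "him")), 3)
})

test_that("nearby error-shifted singletons merge into the supported event", {
  ch <- tibble::tibble(
    read_id = sprintf("r%d", 1:7),
    segment_id = "S1",
    junction_class = factor("J1", levels = c("J1", "J2", "HIM_other",
                                             "outside_HIM")),
    host_subject_id = "host_1",
    junction_on_host = c(rep(500L, 5), 502L, 900L),
    junction_on_circle = c(rep(70L, 5), 69L, 70L),
    orientation = "+", host_flank = "left")
  ev <- call_ies(ch, merge_tolerance = 5)
  expect_equal(nrow(ev), 2)
  expect_equal(ev$support[ev$host_position == 500], 6)
  # without clustering all three positions survive
  expect_equal(nrow(call_ies(ch, merge_tolerance = 0)), 3)
})

test_that("segment_depth averages a bedGraph-style track", {
  seg <- tibble::tibble(contig = "c1", start = 11, end = 20)
  flat <- tibble::tibble(contig = "c1", start = 0L, end = 100L, depth = 10)
  expect_equal(segment_depth(flat, seg), 10)

  half <- tibble::tibble(contig = "c1", start = c(0L, 15L),
                         end = c(15L, 100L), depth = c(0, 20))
  expect_equal(segment_depth(half, seg), 10)

  expect_error(segment_depth(flat, tibble::tibble(contig = "c1",
                                                  start = 5, end = 4)),
               "empty")
  expect_error(segment_depth(flat[flat$start > 1000, ], seg), "cover")
})

test_that("expected chimera counts scale with the length-depth product", {
  expect_equal(expected_outside_him(1e6, 50, 40, 1e6, 50), 40)
  expect_equal(expected_outside_him(1e6, 50, 40, 2e6, 50), 80)
  expect_equal(expected_outside_him(1e6, 50, 10, 7e5, 25), 3.5)
  expect_error(expected_outside_him(0, 50, 10, 1e5, 10), "positive")
})

test_that("depth-IE correlation recovers monotone abundance structure", {
  d <- c(S1 = 5, S2 = 10, S3 = 20, S4 = 40, S5 = 80)
  n <- c(S1 = 2, S2 = 4, S3 = 8, S4 = 16, S5 = 32)
  x <- depth_ie_correlation(d, n)
  expect_equal(x$rho, 1)
  y <- depth_ie_correlation(d, rev(unname(n)) |> setNames(names(n)))
  expect_equal(y$rho, -1)
  expect_warning(z <- depth_ie_correlation(rep(3, 5) |> setNames(names(d)), n),
                 "constant")
  expect_true(z$degenerate)
  expect_error(depth_ie_correlation(d[1:3], n[1:3]), "4 segments")
  # tidy/glance accessors
  expect_equal(nrow(tidy(x)), 5)
  expect_equal(glance(x)$rho, 1)
})

test_that("circle abundance gradients yield a perfect rank correlation", {
  x <- abundance_depth_cor()
  expect_equal(x$rho, 1)
  expect_lt(x$p_value, 0.05)
  expect_true(all(tidy(x)$n_ies > 0))
})
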