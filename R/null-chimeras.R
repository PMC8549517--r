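#' Simulate the random-chimera microhomology null
#'
#' Generates `n_reads` artificial chimeric reads, each the concatenation of
#' a substring drawn from a random location of a random circle and a
#' substring drawn from a random location of the host genome; the two
#' lengths are uniform with both at least `min_side` bp and summing to
#' `read_length`. Each read's two maximal local alignments back to its
#' sources are reconstructed by deterministic exact-match extension of the
#' known source intervals (exact for these error-free substrings), and the
#' resulting hit table is passed through the production classification code
#' path ([select_best_hit()] + [classify_chimeras()]), so the overlap the
#' null reports is measured by the very same code that measures it on real
#' chimeras.
#'
#' @param circles Named character vector of circle sequences.
#' @param host Named character vector of host contig sequences.
#' @param n_reads Number of in-silico reads.
#' @param read_length Read length (150 by default).
#' @param min_side Minimum length of each of the two regions (28 by
#'   default, so each side is alignable on its own).
#' @param seed Integer seed.
#' @param max_len Longest microhomology/insertion tracked individually in
#'   the distribution (longer overlaps pool into the top bin).
#' @return An object of class `mh_distribution`: a tibble with `kind`
#'   (`microhomology` or `insertion`), `length` and `count`, labelled
#'   `expected`, with attributes `stats` (one-sided junction-base match
#'   frequencies: `p_match1` = frequency with which the base following the
#'   junction on the circle matches the base following the junction on the
#'   host, `p_match2` = same for a 2-bp extension) and `chimeras` (the
#'   classified tibble).
#' @export
simulate_null_chimeras <- function(circles, host, n_reads,
                                   read_length = 150, min_side = 28,
                                   seed = 1L, max_len = 13L) {
  stopifnot(length(circles) > 0, length(host) > 0)
  if (n_reads <= 0) abort("n_reads must be positive")
  if (any(nchar(circles) < read_length) || any(nchar(host) < read_length)) {
    abort("all source sequences must be at least read_length long")
  }
  with_seed(derive_seed(seed, "nullchim"), {
    L <- as.integer(read_length)
    a <- sample(seq.int(min_side, L - min_side), n_reads, replace = TRUE)
    b <- L - a
    ci <- sample.int(length(circles), n_reads, replace = TRUE)
    hi <- sample.int(length(host), n_reads, replace = TRUE)
    clen <- nchar(circles)[ci]
    hlen <- nchar(host)[hi]
    K <- as.integer(max_len) + 3L
    # keep K bases of context on both sides of each extracted region
    cs <- floor(runif(n_reads, K + 1, clen - a - K)) |> as.integer()
    hs <- floor(runif(n_reads, K + 1, hlen - b - K)) |> as.integer()

    cseq <- substring(circles[ci], cs, cs + a - 1L)
    hseq <- substring(host[hi], hs, hs + b - 1L)

    # wasp-alignment extension into the host part: circle continuation
    # beyond the junction vs. the host-part prefix
    ext_w <- match_run_vec(substring(circles[ci], cs + a, cs + a + K - 1L),
                           substring(host[hi], hs, hs + K - 1L), K)
    # host-alignment extension into the circle part: host bases before the
    # extracted region vs. the circle-part suffix, both read right-to-left
    ext_h <- match_run_vec(
      rev_str(substring(host[hi], hs - K, hs - 1L)),
      rev_str(substring(circles[ci], cs + a - K, cs + a - 1L)), K)

    wasp_hits <- tibble(
      read_id = sprintf("null_r%d", seq_len(n_reads)),
      subject_id = names(circles)[ci],
      percent_identity = 100, align_length = a + ext_w,
      mismatches = 0L, gap_opens = 0L,
      read_start = 1L, read_end = a + ext_w,
      sbj_start = cs, sbj_end = cs + a - 1L + ext_w,
      evalue = 0, bitscore = 2 * (a + ext_w))
    host_hits <- tibble(
      read_id = wasp_hits$read_id,
      subject_id = names(host)[hi],
      percent_identity = 100, align_length = b + ext_h,
      mismatches = 0L, gap_opens = 0L,
      read_start = a + 1L - ext_h, read_end = L,
      sbj_start = hs - ext_h, sbj_end = hs + b - 1L,
      evalue = 0, bitscore = 2 * (b + ext_h))

    cls <- classify_chimeras(select_best_hit(normalise_hits(wasp_hits)),
                             select_best_hit(normalise_hits(host_hits)),
                             read_length = L)
    acc <- cls[cls$accepted, ]
    dist <- mh_distribution(acc, max_len = max_len, label = "expected")
    attr(dist, "stats") <- list(
      p_match1 = mean(ext_w >= 1),
      p_match2 = mean(ext_w >= 2),
      n_reads = n_reads, n_accepted = nrow(acc),
      reads = tibble(seq = paste0(cseq, hseq), side_wasp = a, side_host = b))
    attr(dist, "chimeras") <- acc
    dist
  })
}

rev_str <- function(x) {
  as.character(Biostrings::reverse(Biostrings::BStringSet(x)))
}

# vectorised leading-match run between equal-length string vectors
match_run_vec <- function(x, y, K) {
  n <- length(x)
  run <- integer(n)
  alive <- rep(TRUE, n)
  for (k in seq_len(K)) {
    m <- alive & substr(x, k, k) == substr(y, k, k) & nchar(x) >= k &
      nchar(y) >= k
    run[m] <- k
    alive <- m
    if (!any(alive)) break
  }
  run
}

#' Tabulate microhomology and insertion lengths from classified chimeras
#'
#' @param chimeras Accepted-chimera tibble.
#' @param max_len Longest length tracked individually (longer overlaps pool
#'   into this bin).
#' @param label `"observed"` or `"expected"`.
#' @return A tibble of class `mh_distribution`: `kind`, `length`, `count`,
#'   `label`. Microhomology counts cover 0..`max_len`; insertion counts
#'   cover 1..5.
#' @export
mh_distribution <- function(chimeras, max_len = 13L, label = "observed") {
  ov <- pmin(chimeras$overlap_len, max_len)
  ins <- chimeras$insert_len
  mh <- tibble(kind = "microhomology", length = 0:max_len,
               count = vapply(0:max_len, function(k) sum(ov == k & ins == 0),
                              numeric(1)))
  inl <- tibble(kind = "insertion", length = 1:5,
                count = vapply(1:5, function(k) sum(ins == k), numeric(1)))
  structure(bind_rows(mh, inl) |> mutate(label = label),
            class = c("mh_distribution", "tbl_df", "tbl", "data.frame"))
}

#' Compare observed and expected microhomology distributions
#'
#' Rescales the expected (null) microhomology counts to the observed total,
#' reports per-length observed/expected ratios, and computes a chi-square
#' goodness-of-fit statistic after pooling upper-tail bins so that every
#' expected count is at least 5.
#'
#' @param observed,expected `mh_distribution` tibbles (only the
#'   `microhomology` rows are compared).
#' @return An object of class `mh_comparison`: a list with `table`
#'   (per-length counts, rescaled expectation and ratio), `statistic`,
#'   `df`, `p_value`.
#' @export
compare_mh_distributions <- function(observed, expected) {
  obs <- observed[observed$kind == "microhomology", ]
  exp <- expected[expected$kind == "microhomology", ]
  tab <- left_join(select(obs, "length", observed = "count"),
                   select(exp, "length", expected_raw = "count"),
                   by = "length")
  tab$expected_raw[is.na(tab$expected_raw)] <- 0
  tot_o <- sum(tab$observed)
  tot_e <- sum(tab$expected_raw)
  if (tot_e == 0) abort("expected distribution is empty")
  tab$expected <- tab$expected_raw * tot_o / tot_e
  tab$ratio <- ifelse(tab$expected > 0, tab$observed / tab$expected, NA_real_)

  # pool upper tail until every expected bin count reaches 5
  o <- tab$observed; e <- tab$expected
  while (length(e) > 1 && (e[length(e)] < 5 || o[length(o)] + e[length(e)] == 0)) {
    n <- length(e)
    e[n - 1] <- e[n - 1] + e[n]; o[n - 1] <- o[n - 1] + o[n]
    e <- e[-n]; o <- o[-n]
  }
  if (all(e < 5)) abort("expected counts too small to test after pooling")
  stat <- sum((o - e)^2 / e)
  df <- length(e) - 1L
  structure(list(table = select(tab, "length", "observed", "expected",
                                "ratio"),
                 statistic = stat, df = df,
                 p_value = pchisq(stat, df, lower.tail = FALSE),
                 pooled_bins = length(e)),
            class = "mh_comparison")
}

#' @export
print.mh_comparison <- function(x, ...) {
  cat("<mh_comparison>\n")
  print(x$table, n = Inf)
  cat(sprintf("chi-square = %.2f, df = %d, p = %.3g\n",
              x$statistic, x$df, x$p_value))
  invisible(x)
}
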