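#' Tile contigs into fixed-width windows
#'
#' Splits each contig into consecutive `window_size`-bp windows starting at
#' position 1; no window spans two contigs, and the sub-window remainder at
#' each contig end is excluded (but accounted for).
#'
#' @param contig_lengths Named integer vector or tibble
#'   (`contig`, `length`).
#' @param window_size Window width in bp (100 kb by default).
#' @return An object of class `window_set`: a tibble (`contig`, `start`,
#'   `end`, 1-based inclusive, all of width `window_size`) with attributes
#'   `excluded` (per-contig remainder tibble), `coverage_fraction`
#'   (retained bp / genome bp) and `window_size`.
#' @export
make_windows <- function(contig_lengths, window_size = 100000) {
  stopifnot(window_size > 0)
  if (is.data.frame(contig_lengths)) {
    contig_lengths <- setNames(contig_lengths$length, contig_lengths$contig)
  }
  win <- lapply(names(contig_lengths), function(ct) {
    len <- contig_lengths[[ct]]
    k <- len %/% window_size
    if (k == 0) return(NULL)
    tibble(contig = ct,
           start = as.integer((seq_len(k) - 1) * window_size + 1),
           end = as.integer(seq_len(k) * window_size))
  })
  windows <- bind_rows(win)
  if (nrow(windows) == 0) {
    windows <- tibble(contig = character(), start = integer(),
                      end = integer())
  }
  rem <- tibble(contig = names(contig_lengths),
                remainder = as.integer(contig_lengths %% window_size))
  total <- sum(as.numeric(contig_lengths))
  retained <- nrow(windows) * as.numeric(window_size)
  structure(windows,
            class = c("window_set", "tbl_df", "tbl", "data.frame"),
            excluded = rem,
            coverage_fraction = if (total > 0) retained / total else NA_real_,
            window_size = window_size)
}

#' Count integration events per window
#'
#' Each event is assigned to the window containing its host position
#' (half-open assignment: position `window_size + 1` falls in the second
#' window). Events landing in the excluded contig-end remainders are
#' counted separately.
#'
#' @param events Event tibble with `host_contig`, `host_position`.
#' @param windows A [make_windows()] window set.
#' @return A tibble with one row per window (`contig`, `start`, `end`,
#'   `count`) carrying attributes `n_excluded` (events in remainders) and
#'   `fraction_in_windows`.
#' @export
window_ie_counts <- function(events, windows) {
  wsize <- attr(windows, "window_size")
  counts <- integer(nrow(windows))
  n_excl <- 0L
  if (nrow(events) > 0) {
    known <- unique(windows$contig)
    excl <- attr(windows, "excluded")
    all_known <- union(known, excl$contig[excl$remainder > 0])
    if (any(!events$host_contig %in% all_known)) {
      bad <- setdiff(unique(events$host_contig), all_known)
      abort(sprintf("events on unknown contig(s): %s",
                    paste(bad, collapse = ", ")))
    }
    idx0 <- (events$host_position - 1L) %/% wsize  # 0-based window index
    key <- paste(events$host_contig, idx0)
    wkey <- paste(windows$contig, (windows$start - 1L) %/% wsize)
    m <- match(key, wkey)
    t <- table(m[!is.na(m)])
    counts[as.integer(names(t))] <- as.integer(t)
    n_excl <- sum(is.na(m))
  }
  out <- windows
  out$count <- counts
  attr(out, "n_excluded") <- n_excl
  attr(out, "fraction_in_windows") <-
    if (nrow(events) > 0) sum(counts) / nrow(events) else NA_real_
  out
}

#' Poisson test for spatial randomness of integration counts
#'
#' Under the null that events land uniformly at random, per-window counts
#' are Poisson with rate `lambda` = mean count. The observed occupancy
#' spectrum (number of windows with k events) is compared to the Poisson
#' expectation by a chi-square goodness-of-fit test with upper-tail classes
#' pooled until every expected class count is at least 5; one degree of
#' freedom is spent on the estimated rate. Also reported is the largest
#' occupancy the null makes plausible: the largest k for which at least
#' half a window is expected.
#'
#' @param counts Integer vector of per-window counts (or a
#'   [window_ie_counts()] tibble).
#' @return An object of class `ie_poisson_test`: list with `lambda`,
#'   `n_windows`, `occupancy` (observed vs expected per class),
#'   `max_plausible_count`, `statistic`, `df`, `p_value`, `degenerate`.
#' @export
poisson_randomness_test <- function(counts) {
  if (is.data.frame(counts)) counts <- counts$count
  n <- length(counts)
  if (n < 2) abort("need at least 2 windows")
  lambda <- mean(counts)
  if (lambda == 0) {
    warn("all window counts are zero: test degenerate")
    return(structure(list(lambda = 0, n_windows = n, occupancy = NULL,
                          max_plausible_count = 0L, statistic = NA_real_,
                          df = NA_integer_, p_value = NA_real_,
                          degenerate = TRUE),
                     class = "ie_poisson_test"))
  }
  kmax <- max(counts)
  obs <- vapply(0:kmax, function(k) sum(counts == k), numeric(1))
  expd <- n * dpois(0:kmax, lambda)
  # the open upper class absorbs the remaining tail mass
  expd[kmax + 1L] <- expd[kmax + 1L] + n * stats::ppois(kmax, lambda,
                                                        lower.tail = FALSE)
  occupancy <- tibble(k = 0:kmax, observed = obs, expected = expd)

  mp <- suppressWarnings(max(which(n * dpois(0:max(kmax, 50), lambda) >= 0.5)) - 1L)
  if (!is.finite(mp)) mp <- 0L

  o <- obs; e <- expd
  while (length(e) > 2 && e[length(e)] < 5) {
    m <- length(e)
    e[m - 1] <- e[m - 1] + e[m]; o[m - 1] <- o[m - 1] + o[m]
    e <- e[-m]; o <- o[-m]
  }
  if (length(e) < 2) {
    warn("too few occupancy classes for a goodness-of-fit test")
    stat <- NA_real_; df <- NA_integer_; p <- NA_real_
  } else {
    stat <- sum((o - e)^2 / e)
    df <- max(1L, length(e) - 2L)  # one df spent estimating lambda
    p <- pchisq(stat, df, lower.tail = FALSE)
  }
  structure(list(lambda = lambda, n_windows = n, occupancy = occupancy,
                 max_plausible_count = mp, statistic = stat, df = df,
                 p_value = p, degenerate = FALSE),
            class = "ie_poisson_test")
}

#' @export
print.ie_poisson_test <- function(x, ...) {
  cat(sprintf("<ie_poisson_test> lambda = %.4f over %d windows\n",
              x$lambda, x$n_windows))
  if (!x$degenerate) {
    cat(sprintf("  chi-square = %.2f, df = %d, p = %.3g; no window expected beyond %d events\n",
                x$statistic, x$df, x$p_value, x$max_plausible_count))
  }
  invisible(x)
}
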