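#' @importFrom rlang %||% abort warn .data
#' @importFrom dplyr mutate filter select arrange group_by ungroup summarise
#'   bind_rows left_join n row_number desc across all_of distinct slice count
#' @importFrom tibble tibble as_tibble
#' @importFrom purrr map map2 pmap map_dbl map_int map_chr
#' @importFrom stats rbinom rpois runif setNames dpois pchisq cor.test
#' @importFrom utils head tail
NULL

DNA_BASES <- c("A", "C", "G", "T")

# Evaluate `code` under a temporary RNG state seeded with `seed`; the caller's
# RNG stream is untouched.
with_seed <- function(seed, code) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  }, add = TRUE)
  set.seed(seed)
  force(code)
}

# Derive a child seed from a parent seed and a stream label, staying within
# 32-bit integer range.
derive_seed <- function(seed, stream) {
  offs <- sum(utf8ToInt(as.character(stream)) * seq_along(utf8ToInt(as.character(stream))))
  as.integer((as.numeric(seed) * 48271 + offs) %% 2147483587L) + 1L
}

#' Generate a random DNA sequence
#'
#' Bases are drawn i.i.d. with the given GC content (A/T and G/C split
#' evenly), so that the probability two random bases match is
#' \eqn{2 (gc/2)^2 + 2 ((1-gc)/2)^2} (= 1/4 at `gc = 0.5`).
#'
#' @param n Sequence length in bp.
#' @param gc GC content in `[0, 1]`.
#' @return A single character string of length `n`.
#' @keywords internal
rand_dna <- function(n, gc = 0.5) {
  if (n <= 0) return("")
  p <- c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)
  paste(sample(DNA_BASES, n, replace = TRUE, prob = p), collapse = "")
}

seq_len_bp <- function(x) nchar(x)

subseq_chr <- function(x, start, end) substr(x, start, end)

# In-place replacement of x[start..start+nchar(value)-1] with value.
replace_subseq <- function(x, start, value) {
  paste0(substr(x, 1L, start - 1L), value,
         substr(x, start + nchar(value), nchar(x)))
}

comp_map <- c(A = "T", C = "G", G = "C", T = "A", N = "N")

revcomp <- function(x) {
  vapply(x, function(s) {
    if (!nzchar(s)) return("")
    paste(rev(comp_map[strsplit(s, "", fixed = TRUE)[[1]]]), collapse = "")
  }, character(1), USE.NAMES = FALSE)
}

# Substitute `k` random positions of `x` with a different base.
mutate_seq <- function(x, k) {
  if (k <= 0) return(x)
  ch <- strsplit(x, "", fixed = TRUE)[[1]]
  pos <- sample.int(length(ch), min(k, length(ch)))
  for (p in pos) ch[p] <- sample(setdiff(DNA_BASES, ch[p]), 1)
  paste(ch, collapse = "")
}

# Leading exact-match run length between two base vectors (stops at the first
# mismatch or at the end of the shorter vector).
match_run <- function(a, b) {
  m <- min(length(a), length(b))
  if (m == 0) return(0L)
  eq <- a[seq_len(m)] == b[seq_len(m)]
  if (all(eq)) m else which(!eq)[1] - 1L
}

# Length of the maximal-score ungapped extension of a local alignment along
# two base vectors, with match reward and mismatch penalty as used by
# `blastn -task blastn` (+2/-3). The extension can run through isolated
# mismatches when enough matches follow; ties resolve to the shortest
# extension reaching the maximum score.
scored_ext <- function(a, b, reward = 2, penalty = -3) {
  m <- min(length(a), length(b))
  if (m == 0) return(0L)
  sc <- cumsum(ifelse(a[seq_len(m)] == b[seq_len(m)], reward, penalty))
  best <- max(0, sc)
  if (best == 0) return(0L)
  which(sc == best)[1]
}

# Maximal-score gapped extension of a local alignment: `a` is the sequence
# the alignment would consume on the read, `b` on the subject, both starting
# at the first position past the anchored alignment. Affine gaps cost
# open + k * extend, scoring as `blastn -task blastn` (+2/-3, 5 + 2k).
# Returns c(i, j): read and subject bases consumed by the best extension
# (shortest such extension on ties).
ext_dp <- function(a, b, reward = 2, penalty = -3,
                   gap_open = 5, gap_extend = 2) {
  la <- length(a); lb <- length(b)
  if (la == 0 || lb == 0) return(c(0L, 0L))
  NEG <- -1e9
  M <- matrix(NEG, la + 1L, lb + 1L)
  Ix <- matrix(NEG, la + 1L, lb + 1L)  # gap in subject (consumes read)
  Iy <- matrix(NEG, la + 1L, lb + 1L)  # gap in read (consumes subject)
  M[1, 1] <- 0
  open1 <- gap_open + gap_extend
  best <- 0; bi <- 0L; bj <- 0L
  for (i in 1:la) {
    Ix[i + 1L, 1L] <- max(M[i, 1L] - open1, Ix[i, 1L] - gap_extend)
    for (j in 1:lb) {
      if (i == 1L) {
        Iy[1L, j + 1L] <- max(M[1L, j] - open1, Iy[1L, j] - gap_extend)
      }
      s <- if (a[i] == b[j]) reward else penalty
      M[i + 1L, j + 1L] <- max(M[i, j], Ix[i, j], Iy[i, j]) + s
      Ix[i + 1L, j + 1L] <- max(M[i, j + 1L] - open1,
                                Ix[i, j + 1L] - gap_extend)
      Iy[i + 1L, j + 1L] <- max(M[i + 1L, j] - open1,
                                Iy[i + 1L, j] - gap_extend)
      if (M[i + 1L, j + 1L] > best) {
        best <- M[i + 1L, j + 1L]; bi <- i; bj <- j
      }
    }
  }
  c(bi, bj)
}

chars <- function(x) {
  if (!nzchar(x)) return(character(0))
  strsplit(x, "", fixed = TRUE)[[1]]
}

# Safe substring of a long sequence, clipped to [1, nchar].
clip_sub <- function(x, start, end) {
  start <- max(1L, start)
  end <- min(nchar(x), end)
  if (end < start) return("")
  substr(x, start, end)
}

is_count <- function(x) is.numeric(x) && length(x) == 1 && !is.na(x) && x >= 0 && x == floor(x)
is_prob <- function(x) is.numeric(x) && all(!is.na(x)) && all(x >= 0) && all(x <= 1)
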