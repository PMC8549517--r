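#' Simulate fixed-length single-end reads from a set of sequences
#'
#' Reads are drawn uniformly along each source at its target fold-coverage
#' (`n = round(depth * length / read_length)` per source), on either strand,
#' with i.i.d. per-base substitution errors. A `pcr_dup_rate` fraction of the
#' pooled reads is then duplicated exactly (identical sequence, `_dupN`
#' suffix on the identifier), emulating PCR duplicates.
#'
#' @param sources A data frame with columns `name`, `seq`, `depth` (and any
#'   extra columns, which are carried through to the truth table).
#' @param read_length Read length in bp.
#' @param error_rate Per-base substitution probability.
#' @param pcr_dup_rate Fraction of reads duplicated.
#' @param seed Integer seed (all randomness local to this call).
#' @param stranded If `TRUE` (default) reads are drawn from both strands.
#' @return A tibble (the read-truth table) with one row per read: `read_id`,
#'   `seq`, `source`, `start`, `end` (1-based inclusive interval on the
#'   source), `strand`, `n_errors`, `is_dup`.
#' @export
simulate_reads <- function(sources, read_length = 150, error_rate = 0,
                           pcr_dup_rate = 0, seed = 1L, stranded = TRUE) {
  stopifnot(is.data.frame(sources),
            all(c("name", "seq", "depth") %in% names(sources)),
            all(sources$depth > 0))
  if (any(nchar(sources$seq) < read_length)) {
    abort("read_length exceeds the length of at least one source sequence")
  }
  with_seed(derive_seed(seed, "reads"), {
    per_source <- purrr::pmap(sources, function(name, seq, depth, ...) {
      len <- nchar(seq)
      n <- round(depth * len / read_length)
      if (n == 0) return(NULL)
      starts <- sample.int(len - read_length + 1L, n, replace = TRUE)
      tibble(read_id = sprintf("%s_r%d", name, seq_len(n)),
             source = name, start = starts,
             end = starts + as.integer(read_length) - 1L,
             seq = substring(seq, starts, starts + read_length - 1L))
    })
    reads <- bind_rows(per_source)
    if (nrow(reads) == 0) {
      return(tibble(read_id = character(), seq = character(),
                    source = character(), start = integer(), end = integer(),
                    strand = character(), n_errors = integer(),
                    is_dup = logical()))
    }
    reads <- finish_reads(reads, read_length, error_rate, pcr_dup_rate,
                          stranded)
    extra <- sources[setdiff(names(sources), c("seq", "depth"))]
    if (ncol(extra) > 1) {
      reads <- left_join(reads, dplyr::rename(extra, source = "name"),
                         by = "source")
    }
    reads
  })
}

# strand assignment, substitution errors and PCR duplication, shared by the
# background-read and junction-read generators (caller provides RNG state)
finish_reads <- function(reads, read_length, error_rate, pcr_dup_rate,
                         stranded = TRUE) {
  n <- nrow(reads)
  reads$strand <- if (stranded) {
    sample(c("+", "-"), n, replace = TRUE)
  } else {
    rep("+", n)
  }
  minus <- reads$strand == "-"
  if (any(minus)) reads$seq[minus] <- revcomp_bulk(reads$seq[minus])
  reads$n_errors <- if (error_rate > 0) {
    rbinom(n, as.integer(read_length), error_rate)
  } else {
    integer(n)
  }
  hit <- which(reads$n_errors > 0)
  for (i in hit) reads$seq[i] <- mutate_seq(reads$seq[i], reads$n_errors[i])
  reads$is_dup <- FALSE
  n_dup <- floor(pcr_dup_rate * n)
  if (n_dup > 0) {
    idx <- sample.int(n, n_dup)
    dups <- reads[idx, ]
    dups$read_id <- paste0(dups$read_id, "_dup1")
    dups$is_dup <- TRUE
    reads <- bind_rows(reads, dups)
  }
  reads
}

revcomp_bulk <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}
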