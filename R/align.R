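#' Parse a 12-column tabular alignment file
#'
#' Reads the classic 12-column tabular alignment dialect (query id, subject
#' id, percent identity, alignment length, mismatches, gap opens, query
#' start/end, subject start/end, e-value, bit score) as produced by
#' `blastn -outfmt 6` and compatible aligners. Rows are normalised so read
#' coordinates ascend; `sbj_start` is the subject coordinate paired with
#' `read_start`, so minus-strand hits have `sbj_start > sbj_end` and
#' `strand == "-"`.
#'
#' @param path Path to the tabular file.
#' @param genome Optional label (e.g. `"wasp"` or `"host"`) stored in a
#'   `genome` column.
#' @return A tibble of alignment hits. Malformed rows are dropped with a
#'   warning naming their line numbers.
#' @export
parse_alignment_table <- function(path, genome = NULL) {
  if (!file.exists(path)) abort(sprintf("alignment file not found: %s", path))
  cols <- c("read_id", "subject_id", "percent_identity", "align_length",
            "mismatches", "gap_opens", "read_start", "read_end",
            "sbj_start", "sbj_end", "evalue", "bitscore")
  raw <- suppressWarnings(
    readr::read_tsv(path, col_names = cols, col_types = "ccdiiiiiiidd",
                    comment = "#", progress = FALSE))
  probs <- readr::problems(raw)
  if (nrow(probs) > 0) {
    bad <- sort(unique(probs$row))
    warn(sprintf("dropped %d malformed alignment row(s): line(s) %s",
                 length(bad), paste(head(bad, 10), collapse = ", ")))
    raw <- raw[-bad, , drop = FALSE]
  }
  bad2 <- !stats::complete.cases(raw[c("read_id", "read_start", "read_end",
                                       "sbj_start", "sbj_end", "bitscore")])
  if (any(bad2)) {
    warn(sprintf("dropped %d alignment row(s) with missing fields: line(s) %s",
                 sum(bad2), paste(head(which(bad2), 10), collapse = ", ")))
    raw <- raw[!bad2, , drop = FALSE]
  }
  if (nrow(raw) == 0 && length(readLines(path, n = 1)) > 0 &&
      nrow(probs) == 0 && !any(bad2)) {
    abort(sprintf("could not parse any alignment rows from %s", path))
  }
  normalise_hits(as_tibble(raw), genome)
}

normalise_hits <- function(hits, genome = NULL) {
  flip <- hits$read_start > hits$read_end
  if (any(flip)) {
    hits[flip, c("read_start", "read_end")] <-
      hits[flip, c("read_end", "read_start")]
    hits[flip, c("sbj_start", "sbj_end")] <-
      hits[flip, c("sbj_end", "sbj_start")]
  }
  hits$strand <- ifelse(hits$sbj_start <= hits$sbj_end, "+", "-")
  if (!is.null(genome)) hits$genome <- genome
  hits
}

has_blast <- function() {
  nzchar(Sys.which("blastn")) && nzchar(Sys.which("makeblastdb"))
}

write_fasta <- function(seqs, path) {
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(seqs), path)
  invisible(path)
}

write_fastq <- function(reads, path) {
  x <- Biostrings::DNAStringSet(setNames(reads$seq, reads$read_id))
  Biostrings::writeXStringSet(
    x, path, format = "fastq",
    qualities = Biostrings::BStringSet(
      vapply(Biostrings::width(x), function(w) strrep("I", w), character(1))))
  invisible(path)
}

#' Align reads against a reference with BLASTN
#'
#' Thin wrapper around `makeblastdb` + `blastn` producing the 12-column
#' tabular dialect consumed by [parse_alignment_table()]. The default task
#' (`blastn`, word size 11) is sensitive enough to recover the short
#' (>= 16 bp) chimera sides the downstream filters require.
#'
#' @param reads A read tibble (columns `read_id`, `seq`), a named character
#'   vector of read sequences, or a path to an existing FASTA/FASTQ file.
#' @param reference Named character vector of reference sequences, or a
#'   FASTA path.
#' @param genome Optional label passed to [parse_alignment_table()].
#' @param task,word_size,evalue,max_target_seqs `blastn` options; the
#'   e-value cutoff follows the motif-search convention of 1e-6 only for
#'   motif work — read alignment uses a permissive default since filtering
#'   happens downstream.
#' @param workdir Scratch directory for the database and output.
#' @return A tibble of normalised alignment hits.
#' @export
align_reads <- function(reads, reference, genome = NULL,
                        task = "blastn", word_size = 11, evalue = 1e-3,
                        max_target_seqs = 5, workdir = tempfile("blast")) {
  if (!has_blast()) abort("BLAST+ (blastn/makeblastdb) not found on PATH")
  dir.create(workdir, recursive = TRUE, showWarnings = FALSE)
  qf <- if (is.character(reads) && length(reads) == 1 && file.exists(reads)) {
    reads
  } else if (is.data.frame(reads)) {
    write_fasta(setNames(reads$seq, reads$read_id),
                file.path(workdir, "query.fa"))
  } else {
    write_fasta(reads, file.path(workdir, "query.fa"))
  }
  rf <- if (is.character(reference) && length(reference) == 1 &&
            file.exists(reference)) {
    reference
  } else {
    write_fasta(reference, file.path(workdir, "ref.fa"))
  }
  db <- file.path(workdir, "refdb")
  st <- system2("makeblastdb",
                c("-in", rf, "-dbtype", "nucl", "-out", db),
                stdout = FALSE, stderr = FALSE)
  if (st != 0) abort("makeblastdb failed")
  out <- file.path(workdir, "hits.tsv")
  st <- system2("blastn",
                c("-task", task, "-word_size", word_size,
                  "-evalue", format(evalue, scientific = TRUE),
                  "-max_target_seqs", max_target_seqs,
                  "-dust", "no", "-outfmt", "6",
                  "-query", qf, "-db", db, "-out", out),
                stdout = FALSE, stderr = FALSE)
  if (st != 0) abort("blastn failed")
  if (file.size(out) == 0) {
    return(normalise_hits(tibble(
      read_id = character(), subject_id = character(),
      percent_identity = double(), align_length = integer(),
      mismatches = integer(), gap_opens = integer(),
      read_start = integer(), read_end = integer(),
      sbj_start = integer(), sbj_end = integer(),
      evalue = double(), bitscore = double()), genome))
  }
  parse_alignment_table(out, genome)
}
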