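#' Read a FASTA file
#'
#' Sequences are upper-cased and line wrapping is removed; record order is
#' preserved. Duplicate record ids and empty files are errors, since every
#' downstream coordinate is keyed by contig id.
#'
#' @param path path to a FASTA file.
#' @return named character vector of sequences (names are the first
#'   whitespace-delimited token of each header).
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stopf("FASTA file not found: %s", path)
  ss <- Biostrings::readBStringSet(path)
  if (length(ss) == 0L) stopf("empty FASTA file: %s", path)
  ids <- sub("\\s.*$", "", names(ss))
  dup <- ids[duplicated(ids)]
  if (length(dup) > 0L)
    stopf("duplicate FASTA id(s): %s", paste(unique(dup), collapse = ", "))
  seqs <- toupper(as.character(ss))
  names(seqs) <- ids
  seqs
}

#' Write sequences to FASTA
#'
#' @param seqs named character vector of sequences.
#' @param path output path.
#' @param width line width for wrapping.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path, width = 70L) {
  stopifnot(!is.null(names(seqs)), all(nzchar(names(seqs))))
  ss <- Biostrings::BStringSet(seqs)
  Biostrings::writeXStringSet(ss, path, width = width)
  invisible(path)
}

#' Read / write FASTQ (Sanger Phred+33)
#'
#' The simulator emits fixed-quality reads; qualities are carried but not
#' used by the mapper (mismatch counting is quality-blind by design).
#'
#' @param path FASTQ path.
#' @return data.frame with columns `id`, `seq`, `qual`.
#' @export
read_fastq <- function(path) {
  if (!file.exists(path)) stopf("FASTQ file not found: %s", path)
  lines <- readLines(path)
  if (length(lines) %% 4L != 0L)
    stopf("FASTQ file %s: line count not a multiple of 4", path)
  n <- length(lines) %/% 4L
  if (n == 0L) stopf("empty FASTQ file: %s", path)
  idx <- seq_len(n)
  ids <- lines[4L * idx - 3L]
  if (!all(startsWith(ids, "@"))) stopf("malformed FASTQ header line")
  data.frame(
    id = sub("\\s.*$", "", sub("^@", "", ids)),
    seq = toupper(lines[4L * idx - 2L]),
    qual = lines[4L * idx],
    stringsAsFactors = FALSE
  )
}

#' @rdname read_fastq
#' @param reads data.frame with columns `id`, `seq` and optionally `qual`
#'   (defaults to uniform "I", Phred 40).
#' @export
write_fastq <- function(reads, path) {
  qual <- reads$qual
  if (is.null(qual)) qual <- vapply(nchar(reads$seq), function(n)
    strrep("I", n), character(1))
  out <- character(4L * nrow(reads))
  idx <- seq_len(nrow(reads))
  out[4L * idx - 3L] <- paste0("@", reads$id)
  out[4L * idx - 2L] <- reads$seq
  out[4L * idx - 1L] <- "+"
  out[4L * idx] <- qual
  writeLines(out, path)
  invisible(path)
}
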