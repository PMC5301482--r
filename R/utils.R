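#' @useDynLib mitosre, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats pbinom runif rbinom setNames
#' @importFrom utils read.table write.table
NULL

DNA_BASES <- c("A", "C", "G", "T")

#' Complement / reverse-complement of DNA strings
#'
#' Vectorised over character strings of A/C/G/T/N (case preserved for
#' upper-case input; all pipeline sequences are upper-case).
#'
#' @param x character vector of DNA strings.
#' @return character vector of the same length.
#' @export
dna_complement <- function(x) chartr("ACGTN", "TGCAN", x)

#' @rdname dna_complement
#' @export
dna_revcomp <- function(x) {
  vapply(x, function(s) {
    paste(rev(strsplit(dna_complement(s), "", fixed = TRUE)[[1]]),
          collapse = "")
  }, character(1), USE.NAMES = FALSE)
}

#' Convert between DNA (genome) and RNA (transcript) base alphabets
#'
#' `dna_to_rna` rewrites T as U; `rna_to_dna` the reverse. RNA-space
#' substitutions are always reported with U, DNA contexts with T.
#'
#' @param x character vector of bases or strings.
#' @return character vector.
#' @export
dna_to_rna <- function(x) chartr("Tt", "Uu", x)

#' @rdname dna_to_rna
#' @export
rna_to_dna <- function(x) chartr("Uu", "Tt", x)

#' RNA-space complement (A<->U, C<->G)
#' @param x character vector of RNA bases/strings.
#' @return character vector.
#' @export
rna_complement <- function(x) chartr("ACGUN", "UGCAN", x)

#' Convert bases between genome space and per-strand RNA space
#'
#' The strand convention at the heart of the pipeline: a genome-space
#' (forward-reference) base is expressed in the transcript's own
#' orientation by keeping it as-is for strand group F and complementing
#' it for strand group R, writing T as U. `rna_to_genome_space` is the
#' inverse. Vectorised over both arguments.
#'
#' @param base character vector of bases.
#' @param strand_group character vector of "F"/"R".
#' @return character vector of converted bases.
#' @export
genome_to_rna_space <- function(base, strand_group) {
  out <- ifelse(strand_group == "R", dna_complement(base), base)
  dna_to_rna(out)
}

#' @rdname genome_to_rna_space
#' @export
rna_to_genome_space <- function(base, strand_group) {
  out <- rna_to_dna(base)
  ifelse(strand_group == "R", dna_complement(out), out)
}

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)

# substring of a linear genome, 1-based inclusive, bounds-checked
genome_window <- function(seq, start, end) {
  if (start < 1L || end > nchar(seq) || start > end)
    stopf("window [%d, %d] outside genome of length %d", start, end, nchar(seq))
  substr(seq, start, end)
}

#' Empty site table
#'
#' The canonical per-site call table: one row per editing-site call,
#' coordinates 1-based, RNA bases written with U.
#'
#' @return zero-row data.frame with the site-table columns.
#' @export
empty_site_table <- function() {
  data.frame(
    contig = character(0), position = integer(0),
    strand_group = character(0), rna_ref = character(0),
    rna_alt = character(0), depth = integer(0), alt_count = integer(0),
    frequency = numeric(0), p_value = numeric(0), sample = character(0),
    stringsAsFactors = FALSE
  )
}
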