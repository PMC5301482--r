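#' Read / write the pipeline's SAM dialect
#'
#' The pipeline's mapper is ungapped and single-end, so the supported SAM
#' dialect is deliberately narrow: flags 0 (mapped, forward strand group),
#' 16 (mapped, reverse strand group) and 4 (unmapped); CIGAR restricted to
#' a single all-match run (`<len>M`). SEQ is stored in genome-forward
#' orientation (reverse-group reads are reverse-complemented by the mapper
#' before writing, per SAM convention). Gapped records are rejected loudly
#' rather than skipped, because silently dropping them would bias pileups.
#'
#' @param path SAM path.
#' @return list with `header` (named integer vector of contig lengths) and
#'   `alignments`: data.frame with columns `read_id`, `contig`, `position`
#'   (1-based leftmost), `strand_group` ("F"/"R", NA for unmapped), `seq`
#'   (genome-forward orientation), `mapped` (logical).
#' @export
read_sam <- function(path) {
  if (!file.exists(path)) stopf("SAM file not found: %s", path)
  lines <- readLines(path)
  hdr <- lines[startsWith(lines, "@")]
  body <- lines[!startsWith(lines, "@") & nzchar(lines)]
  contigs <- integer(0)
  sq <- hdr[startsWith(hdr, "@SQ")]
  if (length(sq) > 0L) {
    fields <- strsplit(sq, "\t", fixed = TRUE)
    sn <- vapply(fields, function(f)
      sub("^SN:", "", grep("^SN:", f, value = TRUE)[1]), character(1))
    ln <- vapply(fields, function(f)
      as.integer(sub("^LN:", "", grep("^LN:", f, value = TRUE)[1])),
      integer(1))
    contigs <- setNames(ln, sn)
  }
  if (length(body) == 0L) {
    return(list(header = contigs, alignments = data.frame(
      read_id = character(0), contig = character(0), position = integer(0),
      strand_group = character(0), seq = character(0), mapped = logical(0),
      stringsAsFactors = FALSE)))
  }
  f <- strsplit(body, "\t", fixed = TRUE)
  nf <- lengths(f)
  if (any(nf < 11L)) stopf("SAM record with fewer than 11 fields")
  get <- function(i) vapply(f, `[[`, character(1), i)
  flag <- as.integer(get(2))
  bad <- setdiff(unique(flag), c(0L, 4L, 16L))
  if (length(bad) > 0L)
    stopf("unsupported SAM flag(s): %s (dialect allows 0, 4, 16)",
          paste(bad, collapse = ", "))
  cigar <- get(6)
  mapped <- flag != 4L
  ok <- grepl("^[0-9]+M$", cigar[mapped])
  if (!all(ok)) {
    badop <- unique(gsub("[0-9]", "", cigar[mapped][!ok]))
    badop <- setdiff(strsplit(paste(badop, collapse = ""), "")[[1]], "M")
    stopf("unsupported CIGAR operator(s): %s (dialect allows only M)",
          paste(badop, collapse = ", "))
  }
  data.frame(
    read_id = get(1),
    contig = ifelse(mapped, get(3), NA_character_),
    position = ifelse(mapped, as.integer(get(4)), NA_integer_),
    strand_group = ifelse(!mapped, NA_character_,
                          ifelse(flag == 16L, "R", "F")),
    seq = toupper(get(10)),
    mapped = mapped,
    stringsAsFactors = FALSE
  ) -> aln
  list(header = contigs, alignments = aln)
}

#' @rdname read_sam
#' @param alignments data.frame as returned in `read_sam()$alignments` (the
#'   mapper's output is compatible).
#' @param header named integer vector of contig lengths for `@SQ` lines.
#' @export
write_sam <- function(alignments, header, path) {
  a <- alignments
  hdr <- c("@HD\tVN:1.6\tSO:unsorted",
           sprintf("@SQ\tSN:%s\tLN:%d", names(header),
                   as.integer(header)))
  if (length(header) == 0L) hdr <- hdr[1]
  mapped <- if (is.null(a$mapped)) rep(TRUE, nrow(a)) else a$mapped
  flag <- ifelse(!mapped, 4L, ifelse(a$strand_group == "R", 16L, 0L))
  recs <- sprintf("%s\t%d\t%s\t%d\t%d\t%s\t*\t0\t0\t%s\t*",
                  a$read_id, flag,
                  ifelse(mapped, a$contig, "*"),
                  ifelse(mapped, a$position, 0L),
                  ifelse(mapped, 60L, 0L),
                  ifelse(mapped, paste0(nchar(a$seq), "M"), "*"),
                  a$seq)
  writeLines(c(hdr, recs), path)
  invisible(path)
}
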