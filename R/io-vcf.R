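#' Read a minimal VCF of DNA variants
#'
#' Parses the eight fixed VCF columns; `DP` and `AF` are taken from INFO
#' when present. Multi-allelic rows are split into one row per ALT allele;
#' a row is an indel iff REF and ALT lengths differ. This is the external
#' route by which indel variants (which the ungapped internal caller cannot
#' produce) enter the SNP-exclusion step.
#'
#' @param path VCF path.
#' @return data.frame: `contig`, `position`, `ref`, `alt`, `is_indel`,
#'   `depth` (NA when DP absent), `frequency` (NA when AF absent).
#' @export
read_vcf_min <- function(path) {
  if (!file.exists(path)) stopf("VCF file not found: %s", path)
  lines <- readLines(path)
  lines <- lines[!startsWith(lines, "#") & nzchar(lines)]
  empty <- data.frame(contig = character(0), position = integer(0),
                      ref = character(0), alt = character(0),
                      is_indel = logical(0), depth = integer(0),
                      frequency = numeric(0), stringsAsFactors = FALSE)
  if (length(lines) == 0L) return(empty)
  f <- strsplit(lines, "\t", fixed = TRUE)
  if (any(lengths(f) < 8L)) stopf("VCF record with fewer than 8 columns")
  col <- function(i) vapply(f, `[[`, character(1), i)
  pos <- as.integer(col(2))
  if (any(is.na(pos)) || any(pos < 1L))
    stopf("VCF POS must be a positive integer")
  info <- col(8)
  info_num <- function(key) {
    m <- regmatches(info, regexec(paste0("(?:^|;)", key, "=([^;]+)"), info))
    vapply(m, function(x) if (length(x) == 2L) as.numeric(x[2]) else NA_real_,
           numeric(1))
  }
  dp <- info_num("DP"); af <- info_num("AF")
  rows <- lapply(seq_along(f), function(i) {
    alts <- strsplit(col(5)[i], ",", fixed = TRUE)[[1]]
    data.frame(contig = col(1)[i], position = pos[i],
               ref = toupper(col(4)[i]), alt = toupper(alts),
               is_indel = nchar(col(4)[i]) != nchar(alts),
               depth = as.integer(dp[i]), frequency = af[i],
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
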