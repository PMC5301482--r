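#' Read / write the per-site call table (TSV)
#'
#' Tab-separated with a header row; lines starting with `#` are comments.
#' Columns are those of a site call: `contig`, `position` (1-based),
#' `strand_group` (F/R), `rna_ref`, `rna_alt` (RNA alphabet, U not T),
#' `depth`, `alt_count`, `frequency`, `p_value`, `sample`.
#'
#' @param path TSV path.
#' @return site-table data.frame.
#' @export
read_site_table <- function(path) {
  if (!file.exists(path)) stopf("site table not found: %s", path)
  d <- read.table(path, header = TRUE, sep = "\t", comment.char = "#",
                  stringsAsFactors = FALSE, colClasses = c(
                    contig = "character", position = "integer",
                    strand_group = "character", rna_ref = "character",
                    rna_alt = "character", depth = "integer",
                    alt_count = "integer", frequency = "numeric",
                    p_value = "numeric", sample = "character"))
  validate_site_table(d)
  d
}

#' @rdname read_site_table
#' @param sites site-table data.frame.
#' @export
write_site_table <- function(sites, path) {
  validate_site_table(sites)
  write.table(sites, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

validate_site_table <- function(d) {
  need <- names(empty_site_table())
  miss <- setdiff(need, names(d))
  if (length(miss) > 0L)
    stopf("site table missing column(s): %s", paste(miss, collapse = ", "))
  if (nrow(d) == 0L) return(invisible(d))
  if (!all(d$strand_group %in% c("F", "R")))
    stopf("strand_group must be F or R")
  if (!all(c(d$rna_ref, d$rna_alt) %in% c("A", "C", "G", "U")))
    stopf("rna_ref/rna_alt must be RNA bases (A/C/G/U)")
  if (any(d$rna_ref == d$rna_alt)) stopf("rna_ref must differ from rna_alt")
  if (any(d$alt_count > d$depth)) stopf("alt_count exceeds depth")
  ok <- d$depth == 0L | abs(d$frequency - d$alt_count / d$depth) < 1e-9
  if (!all(ok)) stopf("frequency inconsistent with alt_count/depth")
  invisible(d)
}
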