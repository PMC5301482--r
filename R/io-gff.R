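#' Read a GFF3 subset of gene models
#'
#' Supports the feature types the mitochondrial annotation uses: `gene`,
#' `CDS`, `tRNA`, `rRNA`, `intron`. Coordinates are 1-based inclusive.
#' Gene identity is taken from the `ID=` attribute for `gene` rows and the
#' `Parent=` (or `ID=`) attribute for the rest. CDS segments of one gene
#' are grouped and stored ordered 5'-to-3' in transcript orientation (for
#' minus-strand genes, descending genomic start).
#'
#' @param path GFF3 path.
#' @return object of class `gene_models`: list with `features` (data.frame:
#'   `seqid`, `type`, `start`, `end`, `strand`, `gene_id`) and `cds`
#'   (named list per gene of data.frames with `start`, `end`, `strand`,
#'   transcript order).
#' @export
read_gff <- function(path) {
  if (!file.exists(path)) stopf("GFF3 file not found: %s", path)
  lines <- readLines(path)
  lines <- lines[!startsWith(lines, "#") & nzchar(lines)]
  if (length(lines) == 0L)
    return(gene_models(data.frame(
      seqid = character(0), type = character(0), start = integer(0),
      end = integer(0), strand = character(0), gene_id = character(0),
      stringsAsFactors = FALSE)))
  f <- strsplit(lines, "\t", fixed = TRUE)
  if (any(lengths(f) < 9L)) stopf("GFF3 record with fewer than 9 columns")
  col <- function(i) vapply(f, `[[`, character(1), i)
  type <- col(3)
  keep <- type %in% c("gene", "CDS", "tRNA", "rRNA", "intron")
  f <- f[keep]; type <- type[keep]
  col <- function(i) vapply(f, `[[`, character(1), i)
  start <- as.integer(col(4)); end <- as.integer(col(5))
  strand <- col(7)
  if (any(is.na(start)) || any(is.na(end)))
    stopf("non-numeric GFF3 coordinates")
  if (any(start > end))
    stopf("GFF3 feature with start > end (coordinates are 1-based inclusive)")
  if (any(start < 1L)) stopf("GFF3 feature with non-positive start")
  if (!all(strand %in% c("+", "-")))
    stopf("unknown GFF3 strand value(s): %s",
          paste(setdiff(unique(strand), c("+", "-")), collapse = ", "))
  attrs <- col(9)
  get_attr <- function(a, key) {
    m <- regmatches(a, regexec(paste0("(?:^|;)", key, "=([^;]+)"), a))
    vapply(m, function(x) if (length(x) == 2L) x[2] else NA_character_,
           character(1))
  }
  id <- get_attr(attrs, "ID")
  parent <- get_attr(attrs, "Parent")
  gene_id <- ifelse(type == "gene", id, ifelse(is.na(parent), id, parent))
  if (any(is.na(gene_id)))
    stopf("GFF3 feature without ID or Parent attribute")
  feats <- data.frame(seqid = col(1), type = type, start = start, end = end,
                      strand = strand, gene_id = gene_id,
                      stringsAsFactors = FALSE)
  gene_models(feats)
}

#' Construct gene models from a feature table
#'
#' @param features data.frame with columns `seqid`, `type`, `start`, `end`,
#'   `strand`, `gene_id`.
#' @return `gene_models` object (see [read_gff()]).
#' @export
gene_models <- function(features) {
  cds <- features[features$type == "CDS", , drop = FALSE]
  cds_by_gene <- split(cds, cds$gene_id)
  cds_by_gene <- lapply(cds_by_gene, function(d) {
    d <- d[order(d$start), , drop = FALSE]
    if (nrow(d) > 1L && any(d$start[-1L] <= d$end[-nrow(d)]))
      stopf("overlapping CDS segments within gene '%s'", d$gene_id[1])
    if (length(unique(d$strand)) != 1L)
      stopf("CDS segments of gene '%s' on mixed strands", d$gene_id[1])
    if (d$strand[1] == "-")
      d <- d[rev(seq_len(nrow(d))), , drop = FALSE]  # transcript order
    rownames(d) <- NULL
    d
  })
  structure(list(features = features, cds = cds_by_gene),
            class = "gene_models")
}

#' @export
print.gene_models <- function(x, ...) {
  cat(sprintf("gene_models: %d features, %d genes with CDS\n",
              nrow(x$features), length(x$cds)))
  invisible(x)
}

#' Write gene models to GFF3
#'
#' @param models `gene_models` object.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_gff <- function(models, path) {
  fe <- models$features
  attr9 <- ifelse(fe$type == "gene",
                  paste0("ID=", fe$gene_id),
                  paste0("ID=", fe$gene_id, ".", tolower(fe$type),
                         ";Parent=", fe$gene_id))
  lines <- sprintf("%s\tmitosre\t%s\t%d\t%d\t.\t%s\t.\t%s",
                   fe$seqid, fe$type, fe$start, fe$end, fe$strand, attr9)
  writeLines(c("##gff-version 3", lines), path)
  invisible(path)
}

#' Spliced CDS sequence and coordinate map for one gene
#'
#' Concatenates a gene's CDS segments in transcript orientation
#' (reverse-complementing minus-strand genes) and records, for each
#' transcript offset, the genomic position it came from.
#'
#' @param genome_seq single contig sequence (character scalar).
#' @param models `gene_models` object.
#' @param gene_id gene identifier.
#' @return list with `seq` (DNA, transcript orientation), `positions`
#'   (integer vector: genomic position of each transcript offset) and
#'   `strand` ("+"/"-").
#' @export
cds_transcript <- function(genome_seq, models, gene_id) {
  segs <- models$cds[[gene_id]]
  if (is.null(segs)) stopf("gene '%s' has no CDS", gene_id)
  parts <- character(nrow(segs)); posl <- vector("list", nrow(segs))
  for (i in seq_len(nrow(segs))) {
    s <- genome_window(genome_seq, segs$start[i], segs$end[i])
    p <- segs$start[i]:segs$end[i]
    if (segs$strand[i] == "-") { s <- dna_revcomp(s); p <- rev(p) }
    parts[i] <- s; posl[[i]] <- p
  }
  list(seq = paste(parts, collapse = ""),
       positions = unlist(posl, use.names = FALSE),
       strand = segs$strand[1])
}
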