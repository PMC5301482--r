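#' Generate a synthetic circular mitogenome with gene models
#'
#' Builds a random reference sequence carrying non-overlapping
#' single-exon CDS genes, roughly half on the minus strand when
#' `both_strands` is set, emulating a small plant mitogenome's two-strand
#' gene layout. Every CDS starts with ATG, ends with a stop codon, has no
#' internal stop, and has length a multiple of 3. Genes keep at least
#' `read_length` away from the circular origin and at least
#' `2 * read_length` from each other, so that downstream read placement
#' can treat the sequence as linear.
#'
#' @param length genome length in bp (>= 5000).
#' @param n_genes number of CDS genes to place.
#' @param both_strands place ~half of the genes on the minus strand.
#' @param seed RNG seed; the output is byte-identical for identical seeds.
#' @param read_length read length the layout must respect (bp).
#' @param gene_length_range range of CDS lengths in codons (inclusive);
#'   sampled uniformly, then multiplied by 3 (plus start/stop handling).
#' @param contig contig name.
#' @return list with `genome` (named character vector, one contig) and
#'   `models` ([gene_models()]).
#' @export
generate_genome <- function(length, n_genes, both_strands = TRUE, seed = 1L,
                            read_length = 100L,
                            gene_length_range = c(120L, 360L),
                            contig = "mito") {
  if (length < 5000L) stopf("genome length must be >= 5000 bp")
  set.seed(seed)
  n_codons <- sample(gene_length_range[1]:gene_length_range[2], n_genes,
                     replace = TRUE)
  gene_len <- 3L * n_codons  # includes start + stop codons
  min_gap <- 2L * read_length
  need <- sum(gene_len) + (n_genes - 1L) * min_gap + 2L * read_length
  if (need > length)
    stopf("cannot fit %d genes (need %d bp, genome %d bp)", n_genes, need,
          length)
  # distribute the slack randomly among the n_genes + 1 gaps
  slack <- length - need
  parts <- as.integer(stats::rmultinom(1, slack, rep(1, n_genes + 1L)))
  background <- paste(sample(DNA_BASES, length, replace = TRUE),
                      collapse = "")
  seqchars <- strsplit(background, "", fixed = TRUE)[[1]]
  strands <- if (both_strands && n_genes > 0L) {
    s <- rep(c("+", "-"), length.out = n_genes)
    sample(s)
  } else rep("+", n_genes)
  feats <- NULL
  cursor <- read_length + parts[1]
  stops <- c("TAA", "TAG", "TGA")
  sense <- setdiff(names(Biostrings::GENETIC_CODE), stops)
  for (i in seq_len(n_genes)) {
    start <- cursor + 1L
    end <- start + gene_len[i] - 1L
    cds <- paste0("ATG",
                  paste(sample(sense, n_codons[i] - 2L, replace = TRUE),
                        collapse = ""),
                  sample(stops, 1L))
    ins <- if (strands[i] == "+") cds else dna_revcomp(cds)
    seqchars[start:end] <- strsplit(ins, "", fixed = TRUE)[[1]]
    gid <- sprintf("gene%02d", i)
    feats <- rbind(feats, data.frame(
      seqid = contig, type = c("gene", "CDS"), start = start, end = end,
      strand = strands[i], gene_id = gid, stringsAsFactors = FALSE))
    cursor <- end + min_gap + parts[i + 1L]
  }
  if (is.null(feats))
    feats <- data.frame(seqid = character(0), type = character(0),
                        start = integer(0), end = integer(0),
                        strand = character(0), gene_id = character(0),
                        stringsAsFactors = FALSE)
  genome <- setNames(paste(seqchars, collapse = ""), contig)
  list(genome = genome, models = gene_models(feats))
}
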