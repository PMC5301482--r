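#' Default editing-frequency distribution
#'
#' A two-component mixture with its mode in the 91--100% bin, the pattern
#' plant mitochondrial editing sites show: most sites are edited in nearly
#' all transcripts, with a tail of partially edited sites.
#'
#' @param n number of frequencies to draw.
#' @param high_weight probability mass of the near-complete component.
#' @param low_range range of the partially-edited component.
#' @return numeric vector of editing frequencies in (0, 1].
#' @export
default_freq_dist <- function(n, high_weight = 0.6, low_range = c(0.3, 0.9)) {
  hi <- runif(n, 0.91, 1.0)
  lo <- runif(n, low_range[1], low_range[2])
  ifelse(runif(n) < high_weight, hi, lo)
}

#' Plant RNA-editing events, SRE pairs and DNA SNPs into a genome
#'
#' Editing events are C-to-U in the transcript's own orientation. Plain
#' (non-symmetric) events sit on the sense strand of a gene, with
#' probability `codon_bias` at a codon position 1 or 2 cytidine of the
#' spliced CDS (where plant mitochondrial C-to-U edits concentrate), else
#' at any gene-body position carrying the required base. Symmetric (SRE)
#' events come in exact mirrored pairs: at a genome-space C the forward
#' group is edited C-to-U and the reverse group G-to-A (both manifest as a
#' genome-space C-to-T mismatch), and conversely at a genome-space G.
#'
#' All events are placed inside gene bodies so that both sense and
#' antisense transcription (see [simulate_reads()]) provide read coverage.
#'
#' @param genome named character vector (one contig) from
#'   [generate_genome()].
#' @param models `gene_models` annotation.
#' @param n_edits number of edited genomic positions (an SRE position
#'   counts once but contributes two strand-level events).
#' @param sre_fraction fraction of edited positions carrying mirrored
#'   pairs, in `[0, 1]`.
#' @param cluster_spec optional list `(n_edits, window)` forcing that many
#'   edited positions inside one window of the given width (bp), to stress
#'   the mapping mismatch budget.
#' @param freq_dist function(n) drawing editing frequencies; default
#'   [default_freq_dist()].
#' @param n_snps number of planted DNA substitution SNPs (positions
#'   disjoint from edits unless `n_snp_overlap > 0`).
#' @param n_snp_overlap number of SNPs deliberately placed on edited
#'   positions, to exercise the SNP-exclusion step.
#' @param codon_bias probability a plain edit targets a codon-1/2 CDS
#'   cytidine.
#' @param snp_freq_choices allele frequencies sampled for SNPs
#'   (heterozygous / fixed).
#' @param seed RNG seed.
#' @return object of class `ground_truth`: list with `edits` (data.frame:
#'   `position`, `strand_group`, `rna_ref`, `rna_alt`,
#'   `editing_frequency`, `is_sre`), `snps` (data.frame: `position`,
#'   `ref`, `alt`, `allele_frequency`, `is_indel`) and `params`.
#' @export
plant_events <- function(genome, models, n_edits, sre_fraction = 0.4,
                         cluster_spec = NULL, freq_dist = default_freq_dist,
                         n_snps = 0L, n_snp_overlap = 0L, codon_bias = 0.8,
                         snp_freq_choices = c(0.5, 1.0), seed = 1L) {
  if (sre_fraction < 0 || sre_fraction > 1)
    stopf("sre_fraction must be in [0, 1]")
  set.seed(seed)
  gseq <- unname(genome[[1]])
  chars <- strsplit(gseq, "", fixed = TRUE)[[1]]
  genes <- unique(models$features[models$features$type == "gene",
                                  c("start", "end", "strand", "gene_id")])
  if (nrow(genes) == 0L) stopf("no genes to plant events into")

  # pool 1: codon-1/2 cytidines of sense transcripts (preferred targets)
  pool_codon <- integer(0)
  # pool 2: any gene-body position whose sense-transcript base is C
  pool_any <- integer(0)
  for (i in seq_len(nrow(genes))) {
    tr <- cds_transcript(gseq, models, genes$gene_id[i])
    tchars <- strsplit(tr$seq, "", fixed = TRUE)[[1]]
    is_c <- tchars == "C"
    cpos <- ((seq_along(tchars) - 1L) %% 3L) + 1L
    pool_codon <- c(pool_codon, tr$positions[is_c & cpos %in% c(1L, 2L)])
    pool_any <- c(pool_any, tr$positions[is_c])
  }
  n_sre <- round(sre_fraction * n_edits)
  n_plain <- n_edits - n_sre

  # choose cluster positions first, if demanded
  cluster_pos <- integer(0)
  if (!is.null(cluster_spec)) {
    kc <- cluster_spec$n_edits; win <- cluster_spec$window
    found <- FALSE
    ord <- sample(nrow(genes))
    for (i in ord) {
      tr <- cds_transcript(gseq, models, genes$gene_id[i])
      tchars <- strsplit(tr$seq, "", fixed = TRUE)[[1]]
      cand <- sort(tr$positions[tchars == "C"])
      if (length(cand) >= kc) {
        for (j in seq_len(length(cand) - kc + 1L)) {
          if (cand[j + kc - 1L] - cand[j] <= win - 1L) {
            cluster_pos <- cand[j:(j + kc - 1L)]
            found <- TRUE; break
          }
        }
      }
      if (found) break
    }
    if (!found)
      stopf("no gene offers %d cytidines within a %d bp window",
            kc, win)
  }

  take <- function(pool, n, used) {
    pool <- setdiff(pool, used)
    if (length(pool) < n)
      stopf("more events requested than eligible positions (%d needed, %d available)",
            n, length(pool))
    sample(pool, n)
  }

  used <- cluster_pos
  n_plain_left <- n_plain - length(cluster_pos)
  if (n_plain_left < 0L)
    stopf("cluster_spec demands more edits than n_edits allows for plain sites")
  n_from_codon <- rbinom(1, n_plain_left, codon_bias)
  n_from_codon <- min(n_from_codon, length(setdiff(pool_codon, used)))
  p1 <- take(pool_codon, n_from_codon, used); used <- c(used, p1)
  p2 <- take(pool_any, n_plain_left - n_from_codon, used)
  used <- c(used, p2)
  plain_pos <- c(cluster_pos, p1, p2)
  sre_pos <- take(pool_any, n_sre, used); used <- c(used, sre_pos)

  # strand group of a sense C->U event: F for + genes, R for - genes
  gene_of <- function(pos) {
    hit <- genes$strand[genes$start <= pos & genes$end >= pos]
    hit[1]
  }
  plain_sg <- vapply(plain_pos, function(p)
    if (gene_of(p) == "+") "F" else "R", character(1))

  edits <- data.frame(position = integer(0), strand_group = character(0),
                      rna_ref = character(0), rna_alt = character(0),
                      editing_frequency = numeric(0), is_sre = logical(0),
                      stringsAsFactors = FALSE)
  if (length(plain_pos) > 0L) {
    edits <- rbind(edits, data.frame(
      position = plain_pos, strand_group = plain_sg,
      rna_ref = "C", rna_alt = "U",
      editing_frequency = freq_dist(length(plain_pos)), is_sre = FALSE,
      stringsAsFactors = FALSE))
  }
  if (n_sre > 0L) {
    # mirrored pair at each SRE position: the strand whose transcript reads
    # C is edited C->U; the opposite group shows the complementary G->A
    base <- chars[sre_pos]
    sg_c <- ifelse(base == "C", "F", "R")  # group seeing C in RNA space
    f_sre <- freq_dist(n_sre); r_sre <- freq_dist(n_sre)
    edits <- rbind(edits,
      data.frame(position = sre_pos, strand_group = sg_c,
                 rna_ref = "C", rna_alt = "U",
                 editing_frequency = f_sre, is_sre = TRUE,
                 stringsAsFactors = FALSE),
      data.frame(position = sre_pos,
                 strand_group = ifelse(sg_c == "F", "R", "F"),
                 rna_ref = "G", rna_alt = "A",
                 editing_frequency = r_sre, is_sre = TRUE,
                 stringsAsFactors = FALSE))
  }
  edits <- edits[order(edits$position, edits$strand_group), ]
  rownames(edits) <- NULL

  # sanity: planted rna_ref must match the genome
  stopifnot(all(rna_to_genome_space(edits$rna_ref, edits$strand_group) ==
                  chars[edits$position]))

  snps <- data.frame(position = integer(0), ref = character(0),
                     alt = character(0), allele_frequency = numeric(0),
                     is_indel = logical(0), stringsAsFactors = FALSE)
  if (n_snps > 0L) {
    n_free <- n_snps - n_snp_overlap
    free_pool <- setdiff(seq_len(nchar(gseq)), used)
    snp_pos <- sample(free_pool, n_free)
    if (n_snp_overlap > 0L) {
      ov <- sample(unique(edits$position), n_snp_overlap)
      snp_pos <- c(snp_pos, ov)
    }
    ref <- chars[snp_pos]
    alt <- vapply(ref, function(b) sample(setdiff(DNA_BASES, b), 1L),
                  character(1), USE.NAMES = FALSE)
    snps <- data.frame(position = snp_pos, ref = ref, alt = alt,
                       allele_frequency = sample(snp_freq_choices,
                                                 length(snp_pos),
                                                 replace = TRUE),
                       is_indel = FALSE, stringsAsFactors = FALSE)
    snps <- snps[order(snps$position), ]
    rownames(snps) <- NULL
  }

  structure(list(edits = edits, snps = snps,
                 params = list(genome_length = nchar(gseq),
                               n_edits = n_edits,
                               sre_fraction = sre_fraction, seed = seed)),
            class = "ground_truth")
}

#' @export
print.ground_truth <- function(x, ...) {
  cat(sprintf(
    "ground_truth: %d edit events at %d positions (%d SRE pairs), %d SNPs\n",
    nrow(x$edits), length(unique(x$edits$position)),
    sum(x$edits$is_sre) %/% 2L, nrow(x$snps)))
  invisible(x)
}
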