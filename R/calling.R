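#' Strand-partitioned pileup of ungapped alignments
#'
#' Tallies, per (position, strand group), the genome-space base of every
#' overlapping read. Bases are counted in forward-genome orientation (the
#' mapper already stores reverse-group reads reverse-complemented). `N`
#' bases contribute no evidence. Positions with zero coverage are absent.
#'
#' @param alignments alignment data.frame (from [map_reads()],
#'   [read_sam()] or a truth SAM); unmapped rows are ignored.
#' @param genome named character vector (one contig), used for bounds.
#' @return data.frame: `position`, `strand_group`, `A`, `C`, `G`, `T`,
#'   `depth`.
#' @export
build_pileup <- function(alignments, genome) {
  a <- alignments
  if (!is.null(a$mapped)) a <- a[a$mapped, , drop = FALSE]
  glen <- nchar(unname(genome[[1]]))
  if (nrow(a) == 0L)
    return(data.frame(position = integer(0), strand_group = character(0),
                      A = integer(0), C = integer(0), G = integer(0),
                      T = integer(0), depth = integer(0),
                      stringsAsFactors = FALSE))
  res <- pileup_cpp(as.integer(a$position), a$strand_group, a$seq, glen)
  out <- data.frame(position = res$position,
                    strand_group = res$strand_group,
                    A = res$A, C = res$C, G = res$G, T = res$T,
                    stringsAsFactors = FALSE)
  out$depth <- out$A + out$C + out$G + out$T
  out
}

#' Pooled, strand-agnostic pileup (for DNA reads)
#'
#' Reads of both orientations are pooled into a single column per
#' position, as a DNA variant caller sees them.
#'
#' @inheritParams build_pileup
#' @return data.frame: `position`, `A`, `C`, `G`, `T`, `depth`.
#' @export
build_pileup_unstranded <- function(alignments, genome) {
  a <- alignments
  if (!is.null(a$mapped)) a <- a[a$mapped, , drop = FALSE]
  a$strand_group <- "F"
  p <- build_pileup(a, genome)
  p$strand_group <- NULL
  p
}

# one-sided exact binomial tail: P(X >= alt | n = depth, p)
binom_tail <- function(alt, depth, p) {
  pbinom(alt - 1L, size = depth, prob = p, lower.tail = FALSE)
}

#' Call RNA-editing sites from a strand-partitioned pileup
#'
#' Per (position, strand group): every non-reference genome-space base is
#' a candidate substitution. A candidate passes if coverage `depth >=
#' c_min`, editing frequency `alt_count/depth >= f_min`, and the
#' one-sided exact binomial tail probability of seeing at least
#' `alt_count` miscalls of that specific base under a uniform sequencing
#' error model (`P(X >= alt_count | n = depth, p = error_rate/3)`) is at
#' most `p_max`. Positions where two or more distinct substitutions pass
#' on one strand group are discarded entirely (multi-type exclusion);
#' the other strand group is judged independently. Surviving calls are
#' reported in RNA space: forward-group bases as-is, reverse-group bases
#' complemented, T written as U.
#'
#' @param pileup from [build_pileup()].
#' @param genome named character vector (one contig).
#' @param c_min minimum coverage (default 5).
#' @param f_min minimum editing frequency (default 0.1).
#' @param p_max maximum binomial tail probability (default 0.05).
#' @param error_rate assumed per-base sequencing error rate of the error
#'   model (default 0.01); each specific miscall has rate `error_rate/3`.
#' @param sample sample label carried into the site table.
#' @param contig contig name.
#' @return site-table data.frame (see [empty_site_table()]).
#' @export
call_editing_sites <- function(pileup, genome, c_min = 5L, f_min = 0.1,
                               p_max = 0.05, error_rate = 0.01,
                               sample = "sample", contig = NULL) {
  if (c_min < 1L || f_min < 0 || f_min > 1 || p_max < 0 || p_max > 1 ||
      error_rate < 0 || error_rate >= 1)
    stopf("caller thresholds out of range")
  if (is.null(contig))
    contig <- if (!is.null(names(genome))) names(genome)[1] else "contig"
  gseq <- unname(genome[[1]])
  if (nrow(pileup) == 0L) return(empty_site_table())
  ref <- substring(gseq, pileup$position, pileup$position)
  is_n <- ref == "N"
  if (any(is_n)) {
    warnf("%d pileup column(s) at reference N skipped", sum(is_n))
    pileup <- pileup[!is_n, , drop = FALSE]
    ref <- ref[!is_n]
  }
  if (nrow(pileup) == 0L) return(empty_site_table())
  p_err <- error_rate / 3
  cnt <- as.matrix(pileup[, DNA_BASES])
  depth <- pileup$depth
  # long form: one row per (column, candidate alt base)
  is_alt <- outer(ref, DNA_BASES, "!=")
  idx <- which(is_alt, arr.ind = TRUE)
  row_i <- idx[, 1]; alt_b <- DNA_BASES[idx[, 2]]
  acnt <- cnt[idx]
  pass <- depth[row_i] >= c_min & acnt > 0L &
    (acnt / depth[row_i]) >= (f_min - 1e-12)
  pv <- rep(NA_real_, length(acnt))
  pv[pass] <- binom_tail(acnt[pass], depth[row_i][pass], p_err)
  pass <- pass & !is.na(pv) & pv <= p_max
  # multi-type exclusion: keep columns where exactly one alt passes
  n_pass <- tabulate(row_i[pass], nbins = nrow(pileup))
  keep <- pass & n_pass[row_i] == 1L
  if (!any(keep)) return(empty_site_table())
  ri <- row_i[keep]
  sg <- pileup$strand_group[ri]
  out <- data.frame(
    contig = contig, position = pileup$position[ri], strand_group = sg,
    rna_ref = genome_to_rna_space(ref[ri], sg),
    rna_alt = genome_to_rna_space(alt_b[keep], sg),
    depth = depth[ri], alt_count = acnt[keep],
    frequency = acnt[keep] / depth[ri], p_value = pv[keep],
    sample = sample, stringsAsFactors = FALSE)
  out <- out[order(out$position, out$strand_group), ]
  rownames(out) <- NULL
  out
}

#' Call DNA substitution variants from a pooled pileup
#'
#' Substitutions only (the ungapped mapper yields no indel evidence;
#' indels enter via [read_vcf_min()]). Variants are emitted for any
#' non-reference base seen at least `min_report` times; the
#' `high_quality` flag marks those meeting coverage >= `c_min` and
#' frequency >= `f_min`, which are the ones the editing-site exclusion
#' uses.
#'
#' @param dna_pileup from [build_pileup_unstranded()].
#' @param genome named character vector (one contig).
#' @param c_min minimum coverage for high quality (default 10).
#' @param f_min minimum variant frequency for high quality (default 0.1).
#' @param min_report minimum alt reads for a row to be reported at all.
#' @return data.frame: `position`, `ref`, `alt`, `depth`,
#'   `allele_frequency`, `is_indel`, `high_quality`.
#' @export
call_snps <- function(dna_pileup, genome, c_min = 10L, f_min = 0.1,
                      min_report = 2L) {
  gseq <- unname(genome[[1]])
  empty <- data.frame(position = integer(0), ref = character(0),
                      alt = character(0), depth = integer(0),
                      allele_frequency = numeric(0), is_indel = logical(0),
                      high_quality = logical(0), stringsAsFactors = FALSE)
  if (nrow(dna_pileup) == 0L) return(empty)
  ref <- substring(gseq, dna_pileup$position, dna_pileup$position)
  cnt <- as.matrix(dna_pileup[, DNA_BASES])
  idx <- which(outer(ref, DNA_BASES, "!="), arr.ind = TRUE)
  ri <- idx[, 1]; alt_b <- DNA_BASES[idx[, 2]]
  acnt <- cnt[idx]
  keep <- acnt >= min_report
  if (!any(keep)) return(empty)
  ri <- ri[keep]; alt_b <- alt_b[keep]; acnt <- acnt[keep]
  depth <- dna_pileup$depth[ri]
  freq <- acnt / depth
  out <- data.frame(
    position = dna_pileup$position[ri], ref = ref[ri], alt = alt_b,
    depth = depth, allele_frequency = freq, is_indel = FALSE,
    high_quality = depth >= c_min & freq >= (f_min - 1e-12),
    stringsAsFactors = FALSE)
  out <- out[order(out$position, out$alt), ]
  rownames(out) <- NULL
  out
}

#' Convert external VCF rows to the SNP-site table
#'
#' Rows without DP/AF annotations are taken at face value as
#' high-quality (they are user-asserted variants); annotated rows are
#' held to the same thresholds as [call_snps()].
#'
#' @param vcf data.frame from [read_vcf_min()].
#' @inheritParams call_snps
#' @return SNP-site data.frame as in [call_snps()].
#' @export
snp_sites_from_vcf <- function(vcf, c_min = 10L, f_min = 0.1) {
  hq <- (is.na(vcf$depth) | vcf$depth >= c_min) &
    (is.na(vcf$frequency) | vcf$frequency >= (f_min - 1e-12))
  data.frame(position = vcf$position, ref = vcf$ref, alt = vcf$alt,
             depth = vcf$depth, allele_frequency = vcf$frequency,
             is_indel = vcf$is_indel, high_quality = hq,
             stringsAsFactors = FALSE)
}

#' Exclude editing sites overlapping high-quality DNA variants
#'
#' An apparent editing site that coincides with a genomic variant is a
#' DNA polymorphism read through into RNA, not editing. A site is
#' excluded iff its position equals a high-quality substitution SNP
#' position or falls within the reference span of a high-quality indel
#' (positions `position .. position + nchar(ref) - 1`).
#'
#' @param editing_sites site-table data.frame.
#' @param snp_sites SNP-site data.frame ([call_snps()] /
#'   [snp_sites_from_vcf()]).
#' @return list with `kept` and `excluded` site tables (exact partition).
#' @export
exclude_snp_overlaps <- function(editing_sites, snp_sites) {
  hq <- snp_sites[snp_sites$high_quality, , drop = FALSE]
  if (nrow(hq) == 0L || nrow(editing_sites) == 0L)
    return(list(kept = editing_sites,
                excluded = editing_sites[0, , drop = FALSE]))
  span_end <- hq$position + ifelse(hq$is_indel, nchar(hq$ref) - 1L, 0L)
  bad <- vapply(editing_sites$position, function(p)
    any(hq$position <= p & span_end >= p), logical(1))
  list(kept = editing_sites[!bad, , drop = FALSE],
       excluded = editing_sites[bad, , drop = FALSE])
}

#' Consensus-based site discovery (assembly-method stand-in)
#'
#' The dominant-allele counterpart of the mapping-based caller: per
#' (position, strand group) with coverage >= `c_min`, the consensus base
#' is the strict-majority base (> 50% of depth); a consensus differing
#' from the reference is a site. At desk scale this reproduces what a
#' strand-specific assembler followed by genome comparison yields: the
#' dominant RNA state per position, blind to minor-frequency editing.
#' Exact 50/50 columns have no consensus and yield no site.
#'
#' @inheritParams call_editing_sites
#' @return site-table data.frame; `p_value` is `NA` (no test is
#'   involved).
#' @export
consensus_sites <- function(pileup, genome, c_min = 5L, sample = "consensus",
                            contig = NULL) {
  if (is.null(contig))
    contig <- if (!is.null(names(genome))) names(genome)[1] else "contig"
  gseq <- unname(genome[[1]])
  if (nrow(pileup) == 0L) return(empty_site_table())
  keep <- pileup$depth >= c_min
  pu <- pileup[keep, , drop = FALSE]
  if (nrow(pu) == 0L) return(empty_site_table())
  cnt <- as.matrix(pu[, DNA_BASES])
  top <- max.col(cnt, ties.method = "first")
  top_cnt <- cnt[cbind(seq_len(nrow(cnt)), top)]
  has_majority <- top_cnt * 2L > pu$depth
  ref <- substring(gseq, pu$position, pu$position)
  cons <- DNA_BASES[top]
  hit <- has_majority & cons != ref & ref != "N"
  if (!any(hit)) return(empty_site_table())
  pu <- pu[hit, , drop = FALSE]; ref <- ref[hit]; cons <- cons[hit]
  top_cnt <- top_cnt[hit]
  out <- data.frame(
    contig = contig, position = pu$position,
    strand_group = pu$strand_group,
    rna_ref = genome_to_rna_space(ref, pu$strand_group),
    rna_alt = genome_to_rna_space(cons, pu$strand_group),
    depth = pu$depth, alt_count = top_cnt,
    frequency = top_cnt / pu$depth, p_value = NA_real_, sample = sample,
    stringsAsFactors = FALSE)
  out <- out[order(out$position, out$strand_group), ]
  rownames(out) <- NULL
  out
}

#' Pool alignments from several samples
#'
#' Concatenates per-sample alignment sets for combined calling (the
#' pooled-tissue analysis), preserving sample provenance in a `sample`
#' column. All samples must be aligned to the same reference contig set.
#'
#' @param ... named alignment data.frames, or a single named list of
#'   them.
#' @return one alignment data.frame with a `sample` column.
#' @export
pool_samples <- function(...) {
  args <- list(...)
  if (length(args) == 1L && is.list(args[[1]]) &&
      !is.data.frame(args[[1]])) args <- args[[1]]
  if (is.null(names(args)) || any(!nzchar(names(args))))
    names(args) <- sprintf("sample%d", seq_along(args))
  contigs <- lapply(args, function(a)
    sort(unique(a$contig[!is.na(a$contig)])))
  nonempty <- contigs[vapply(contigs, length, integer(1)) > 0L]
  if (length(unique(nonempty)) > 1L)
    stopf("samples aligned to different references cannot be pooled")
  out <- do.call(rbind, lapply(names(args), function(nm) {
    a <- args[[nm]]
    if (nrow(a) > 0L) a$sample <- nm else a$sample <- character(0)
    a
  }))
  rownames(out) <- NULL
  out
}
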