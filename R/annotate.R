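#' Amino acids treated as hydrophobic
#'
#' Default membership used by [hydrophobicity_shift()]; kept as a
#' constant so the reported shift can be probed under alternative
#' definitions.
#' @export
HYDROPHOBIC_AA <- c("A", "V", "L", "I", "P", "F", "M", "W", "G", "C")

# region + gene + orientation for one (position, strand_group)
locate_one <- function(position, strand_group, models) {
  fe <- models$features
  hit <- fe[fe$start <= position & fe$end >= position, , drop = FALSE]
  sub <- hit[hit$type != "gene", , drop = FALSE]
  genes_here <- unique(sub$gene_id)
  if (length(genes_here) > 1L)
    stopf("position %d lies in features of multiple genes (%s); precedence undefined",
          position, paste(genes_here, collapse = ", "))
  if (nrow(sub) == 0L) {
    return(list(region = "intergenic", gene_id = NA_character_,
                orientation = if (strand_group == "F") "forward"
                              else "reverse"))
  }
  prec <- c("CDS", "intron", "tRNA", "rRNA")
  region <- prec[min(match(sub$type, prec))]
  gstrand <- sub$strand[1]
  sense <- (strand_group == "F") == (gstrand == "+")
  list(region = region, gene_id = genes_here,
       orientation = if (sense) "sense" else "antisense")
}

#' Locate a site in its genomic context
#'
#' Region assignment by coordinate containment with precedence CDS >
#' intron > tRNA/rRNA > intergenic. Genic sites are sense when the strand
#' group matches the gene's coding strand; intergenic sites are labelled
#' forward/reverse by strand group. Overlapping genes at the queried
#' position are an error (no precedence is defined between genes).
#'
#' @param site one-row site table (or list with `position`,
#'   `strand_group`).
#' @param models `gene_models`.
#' @return list with `region`, `gene_id`, `orientation`.
#' @export
locate_site <- function(site, models) {
  locate_one(site$position[1], site$strand_group[1], models)
}

# codon-level consequence of substituting rna_alt at cds_offset of a
# spliced DNA CDS (transcript orientation)
codon_fields <- function(cds_seq, cds_offset, rna_alt) {
  len <- nchar(cds_seq)
  if (len %% 3L != 0L) stopf("CDS length %d not divisible by 3", len)
  if (cds_offset < 1L || cds_offset > len)
    stopf("cds_offset %d outside CDS of length %d", cds_offset, len)
  codon_index <- (cds_offset - 1L) %/% 3L + 1L
  codon_position <- (cds_offset - 1L) %% 3L + 1L
  ref_codon_dna <- substr(cds_seq, 3L * codon_index - 2L, 3L * codon_index)
  alt_codon_dna <- ref_codon_dna
  substr(alt_codon_dna, codon_position, codon_position) <-
    rna_to_dna(rna_alt)
  code <- Biostrings::GENETIC_CODE
  ref_aa <- unname(code[ref_codon_dna])
  alt_aa <- unname(code[alt_codon_dna])
  ref_codon <- dna_to_rna(ref_codon_dna)
  alt_codon <- dna_to_rna(alt_codon_dna)
  effect <-
    if (ref_aa == alt_aa) "silent"
    else if (codon_index == 1L && alt_codon == "AUG") "start_gain"
    else if (alt_aa == "*") "stop_gain"
    else if (ref_aa == "*") "stop_loss"
    else "missense"
  list(codon_index = codon_index, codon_position = codon_position,
       ref_codon = ref_codon, alt_codon = alt_codon,
       ref_aa = ref_aa, alt_aa = alt_aa, effect = effect)
}

#' Codon-level consequence of one CDS sense site
#'
#' Computes the codon index/position of the site in the spliced
#' transcript, the reference and edited codons (RNA alphabet), the amino
#' acids under the standard genetic code, and the effect class: `silent`
#' when the amino acid is unchanged; `start_gain` when the edit turns
#' codon 1 into AUG (the mechanism by which an ACG start becomes a
#' canonical initiation codon); `stop_gain` / `stop_loss` when a stop is
#' created or destroyed; otherwise `missense`.
#'
#' @param site one-row site table of a CDS, sense-orientation call.
#' @param genome named character vector (one contig).
#' @param models `gene_models`.
#' @param gene_id the gene containing the site.
#' @return list of codon fields (see [annotate_sites()] columns).
#' @export
codon_effect <- function(site, genome, models, gene_id) {
  tr <- cds_transcript(unname(genome[[1]]), models, gene_id)
  off <- match(site$position[1], tr$positions)
  if (is.na(off)) stopf("site position %d not in CDS of gene '%s'",
                        site$position[1], gene_id)
  codon_fields(tr$seq, off, site$rna_alt[1])
}

#' Annotate a site table with context and codon consequences
#'
#' Adds region / gene / orientation (see [locate_site()]) to every site;
#' CDS sites additionally get the 1-based spliced-CDS offset, and sense
#' CDS sites the codon fields and effect (see [codon_effect()]).
#' Antisense and non-coding sites get effect `noncoding`. CDS sites are
#' named `<gene>-<cds_offset>` (the conventional naming for plant
#' mitochondrial editing sites); other sites
#' `<contig>:<position>:<strand_group>`.
#'
#' @param sites site-table data.frame.
#' @param genome named character vector (one contig).
#' @param models `gene_models`.
#' @return the site table with annotation columns appended.
#' @export
annotate_sites <- function(sites, genome, models) {
  n <- nrow(sites)
  add <- data.frame(region = character(n), gene_id = NA_character_,
                    orientation = character(n),
                    cds_offset = NA_integer_, codon_index = NA_integer_,
                    codon_position = NA_integer_,
                    ref_codon = NA_character_, alt_codon = NA_character_,
                    ref_aa = NA_character_, alt_aa = NA_character_,
                    effect = "noncoding", site_name = NA_character_,
                    stringsAsFactors = FALSE)
  gseq <- unname(genome[[1]])
  tr_cache <- list()
  for (i in seq_len(n)) {
    loc <- locate_one(sites$position[i], sites$strand_group[i], models)
    add$region[i] <- loc$region
    add$gene_id[i] <- loc$gene_id
    add$orientation[i] <- loc$orientation
    if (loc$region == "CDS") {
      gid <- loc$gene_id
      if (is.null(tr_cache[[gid]]))
        tr_cache[[gid]] <- cds_transcript(gseq, models, gid)
      tr <- tr_cache[[gid]]
      off <- match(sites$position[i], tr$positions)
      add$cds_offset[i] <- off
      add$site_name[i] <- paste0(gid, "-", off)
      if (loc$orientation == "sense") {
        cf <- codon_fields(tr$seq, off, sites$rna_alt[i])
        add$codon_index[i] <- cf$codon_index
        add$codon_position[i] <- cf$codon_position
        add$ref_codon[i] <- cf$ref_codon
        add$alt_codon[i] <- cf$alt_codon
        add$ref_aa[i] <- cf$ref_aa
        add$alt_aa[i] <- cf$alt_aa
        add$effect[i] <- cf$effect
      }
    }
    if (is.na(add$site_name[i]))
      add$site_name[i] <- paste(sites$contig[i], sites$position[i],
                                sites$strand_group[i], sep = ":")
  }
  cbind(sites, add)
}

#' Hydrophobicity shift of edited codons
#'
#' Over the affected residues of C-to-U sense CDS sites: the percentage
#' that are hydrophobic before versus after editing. Stop codons are
#' excluded from the respective denominator.
#'
#' @param annotated annotated site table ([annotate_sites()]).
#' @param hydrophobic amino-acid set treated as hydrophobic.
#' @return named numeric vector `c(before = %, after = %)`.
#' @export
hydrophobicity_shift <- function(annotated,
                                 hydrophobic = HYDROPHOBIC_AA) {
  s <- annotated[annotated$region == "CDS" &
                   annotated$orientation == "sense" &
                   annotated$rna_ref == "C" & annotated$rna_alt == "U" &
                   !is.na(annotated$ref_aa), , drop = FALSE]
  if (nrow(s) == 0L) stopf("no C-to-U sense CDS sites to evaluate")
  before_den <- s$ref_aa != "*"
  after_den <- s$alt_aa != "*"
  c(before = 100 * sum(s$ref_aa %in% hydrophobic & before_den) /
      sum(before_den),
    after = 100 * sum(s$alt_aa %in% hydrophobic & after_den) /
      sum(after_den))
}

FREQ_BIN_LABELS <- c("1-10%", "11-20%", "21-30%", "31-40%", "41-50%",
                     "51-60%", "61-70%", "71-80%", "81-90%", "91-100%")

#' Substitution-type and frequency summaries
#'
#' Counts per the 12 possible RNA-space substitution types, split by
#' strand group, plus a ten-bin editing-frequency histogram per strand
#' group (bins (0, 0.1], ..., (0.9, 1.0], labelled 1-10% through
#' 91-100%).
#'
#' @param sites site-table data.frame.
#' @return list with `types` (data.frame `type`, `F`, `R`) and
#'   `freq_bins` (data.frame `bin`, `F`, `R`).
#' @export
type_frequency_summary <- function(sites) {
  rna <- c("A", "C", "G", "U")
  types <- expand.grid(ref = rna, alt = rna, stringsAsFactors = FALSE)
  types <- types[types$ref != types$alt, ]
  type_lab <- sort(paste0(types$ref, ">", types$alt))
  site_type <- paste0(sites$rna_ref, ">", sites$rna_alt)
  count_by <- function(sg) {
    t <- table(factor(site_type[sites$strand_group == sg],
                      levels = type_lab))
    as.integer(t)
  }
  types_df <- data.frame(type = type_lab, F = count_by("F"),
                         R = count_by("R"), stringsAsFactors = FALSE)
  binned <- cut(sites$frequency, breaks = seq(0, 1, 0.1),
                labels = FREQ_BIN_LABELS, include.lowest = FALSE)
  bin_by <- function(sg)
    as.integer(table(binned[sites$strand_group == sg]))
  bins_df <- data.frame(bin = FREQ_BIN_LABELS, F = bin_by("F"),
                        R = bin_by("R"), stringsAsFactors = FALSE)
  list(types = types_df, freq_bins = bins_df)
}

#' Extract upstream sequence windows around editing sites
#'
#' For motif analysis: the transcript-orientation window from -`span`
#' through 0 (the edited base itself), i.e. `span + 1` bases ending at
#' the site. Forward-group sites take the forward genome; reverse-group
#' sites the reverse complement of the downstream genomic window.
#' Windows that would run off the genome end are dropped with a warning.
#'
#' @param sites site-table data.frame (annotated or raw; `site_name`
#'   used for FASTA ids when present).
#' @param genome named character vector (one contig).
#' @param span upstream extent in bases (default 25).
#' @return named character vector of windows (FASTA-ready, see
#'   [write_fasta()]).
#' @export
extract_upstream_windows <- function(sites, genome, span = 25L) {
  gseq <- unname(genome[[1]])
  glen <- nchar(gseq)
  ids <- if (!is.null(sites$site_name)) sites$site_name
         else paste(sites$contig, sites$position, sites$strand_group,
                    sep = ":")
  out <- character(0)
  dropped <- 0L
  for (i in seq_len(nrow(sites))) {
    p <- sites$position[i]
    if (sites$strand_group[i] == "F") {
      if (p - span < 1L) { dropped <- dropped + 1L; next }
      w <- substr(gseq, p - span, p)
    } else {
      if (p + span > glen) { dropped <- dropped + 1L; next }
      w <- dna_revcomp(substr(gseq, p, p + span))
    }
    out[ids[i]] <- w
  }
  if (dropped > 0L)
    warnf("%d window(s) truncated at genome ends were dropped", dropped)
  out
}
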