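#' Pair per-strand editing calls into symmetrical RNA-editing events
#'
#' A symmetrical RNA-editing (SRE) event is a genomic position where the
#' transcripts of both strands are edited. With `require_mirror = TRUE`
#' (the default) the two calls must be exact complements in RNA space —
#' e.g. C-to-U on the forward group paired with G-to-A on the reverse
#' group, the combination seen in strand-specific validation traces; with
#' `require_mirror = FALSE` any co-edited position pairs. Both members
#' must individually have passed all caller thresholds (they are caller
#' output). One pair per genomic position; output sorted by position.
#'
#' @param forward_sites site table of strand group F calls.
#' @param reverse_sites site table of strand group R calls.
#' @param require_mirror demand complementary substitution types.
#' @return data.frame: `position`, `f_rna_ref`, `f_rna_alt`,
#'   `f_frequency`, `r_rna_ref`, `r_rna_alt`, `r_frequency`, `mirror`.
#' @export
pair_sre <- function(forward_sites, reverse_sites, require_mirror = TRUE) {
  f <- forward_sites[forward_sites$strand_group == "F", , drop = FALSE]
  r <- reverse_sites[reverse_sites$strand_group == "R", , drop = FALSE]
  if (anyDuplicated(f$position) || anyDuplicated(r$position))
    stopf("duplicate calls at one (position, strand group); input is not post multi-type filtering")
  common <- intersect(f$position, r$position)
  fi <- f[match(common, f$position), , drop = FALSE]
  ri <- r[match(common, r$position), , drop = FALSE]
  mirror <- fi$rna_ref == rna_complement(ri$rna_ref) &
    fi$rna_alt == rna_complement(ri$rna_alt)
  keep <- if (require_mirror) mirror else rep(TRUE, length(common))
  out <- data.frame(position = common,
                    f_rna_ref = fi$rna_ref, f_rna_alt = fi$rna_alt,
                    f_frequency = fi$frequency,
                    r_rna_ref = ri$rna_ref, r_rna_alt = ri$rna_alt,
                    r_frequency = ri$frequency,
                    mirror = mirror, stringsAsFactors = FALSE)
  out <- out[keep, , drop = FALSE]
  out <- out[order(out$position), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Classify why a site is absent (or present) in one sample
#'
#' For a site of interest and one sample's pileup: `no_coverage` if the
#' (position, strand group) column is absent or has depth 0;
#' `covered_but_failed` if reads cover it but no substitution survives
#' the caller thresholds; `passed` if a call would be emitted.
#'
#' @param position genomic position.
#' @param strand_group "F" or "R".
#' @param pileup the sample's stranded pileup.
#' @param genome named character vector (one contig).
#' @inheritParams call_editing_sites
#' @return one of `"passed"`, `"covered_but_failed"`, `"no_coverage"`.
#' @export
classify_absence <- function(position, strand_group, pileup, genome,
                             c_min = 5L, f_min = 0.1, p_max = 0.05,
                             error_rate = 0.01) {
  col <- pileup[pileup$position == position &
                  pileup$strand_group == strand_group, , drop = FALSE]
  if (nrow(col) == 0L || col$depth[1] == 0L) return("no_coverage")
  calls <- call_editing_sites(col, genome, c_min = c_min, f_min = f_min,
                              p_max = p_max, error_rate = error_rate)
  if (nrow(calls) > 0L) "passed" else "covered_but_failed"
}

#' Venn partition of site sets across samples
#'
#' Sites are keyed by (position, strand group, substitution). Counts are
#' reported for every non-empty membership region; region counts sum to
#' the size of the union.
#'
#' @param site_sets named list of site tables.
#' @return data.frame: `region` (sample names joined by "&"), `count`.
#' @export
venn_partition <- function(site_sets) {
  stopifnot(length(site_sets) >= 1L, !is.null(names(site_sets)))
  keys <- lapply(site_sets, function(s)
    unique(paste(s$position, s$strand_group, s$rna_ref, s$rna_alt,
                 sep = ":")))
  all_keys <- unique(unlist(keys))
  member <- vapply(keys, function(k) all_keys %in% k,
                   logical(length(all_keys)))
  if (length(all_keys) == 1L) member <- matrix(member, nrow = 1L,
                                               dimnames = list(NULL,
                                                 names(site_sets)))
  region <- apply(member, 1L, function(m)
    paste(names(site_sets)[m], collapse = "&"))
  agg <- table(region)
  nm <- names(site_sets)
  # all 2^n - 1 regions, in subset order, zero-filled
  subsets <- unlist(lapply(seq_along(nm), function(k)
    utils::combn(nm, k, paste, collapse = "&", simplify = FALSE)),
    use.names = FALSE)
  data.frame(region = subsets,
             count = as.integer(ifelse(subsets %in% names(agg),
                                       agg[subsets], 0L)),
             stringsAsFactors = FALSE)
}
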