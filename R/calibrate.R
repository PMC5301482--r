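site_keys <- function(sites) {
  unique(paste(sites$position, sites$strand_group, sites$rna_ref,
               sites$rna_alt, sep = ":"))
}

#' Sensitivity and specificity of one site set against another
#'
#' The mapping-based caller (method 1) is scored against the
#' consensus/assembly caller (method 2):
#' sensitivity = |M1 and M2| / |M2|, specificity = |M1 and M2| / |M1|.
#' Sites are keyed by (position, strand group, substitution).
#'
#' @param m1_sites,m2_sites site tables.
#' @return named numeric vector `c(sensitivity =, specificity =)`.
#' @export
sensitivity_specificity <- function(m1_sites, m2_sites) {
  k1 <- site_keys(m1_sites); k2 <- site_keys(m2_sites)
  if (length(k2) == 0L) stopf("sensitivity undefined: method-2 set empty")
  if (length(k1) == 0L) stopf("specificity undefined: method-1 set empty")
  shared <- length(intersect(k1, k2))
  c(sensitivity = shared / length(k2), specificity = shared / length(k1))
}

#' Grid the mapper's mismatch budget and score each run
#'
#' For each budget k the full mapping-based chain is re-run (map, strand
#' split, pileup, editing-site calling) to give the method-1 set; the
#' method-2 set is computed once, from the mapping at the largest k, by
#' strict-majority consensus ([consensus_sites()]). Degenerate rows
#' (empty method-1 set, where specificity is undefined) are retained
#' with `NA` scores so the full grid is always visible.
#'
#' @param reads read data.frame (`id`, `seq`) or character vector.
#' @param genome named character vector (one contig).
#' @param k_values ascending mismatch budgets (default 2:10).
#' @param c_min,f_min,p_max,error_rate caller thresholds (see
#'   [call_editing_sites()]).
#' @return data.frame: `k`, `n_method1`, `n_method2`, `n_shared`,
#'   `sensitivity`, `specificity`, `harmonic_mean`.
#' @export
run_grid <- function(reads, genome, k_values = 2:10, c_min = 5L,
                     f_min = 0.1, p_max = 0.05, error_rate = 0.01) {
  if (length(k_values) == 0L) stopf("k_values must be non-empty")
  if (is.unsorted(k_values, strictly = TRUE))
    stopf("k_values must be ascending")
  call_at_k <- function(k) {
    aln <- map_reads(reads, genome, max_mismatch = k)
    pu <- build_pileup(aln, genome)
    list(pileup = pu,
         sites = call_editing_sites(pu, genome, c_min = c_min,
                                    f_min = f_min, p_max = p_max,
                                    error_rate = error_rate))
  }
  runs <- lapply(k_values, call_at_k)
  m2 <- consensus_sites(runs[[length(runs)]]$pileup, genome,
                        c_min = c_min)
  k2 <- site_keys(m2)
  rows <- lapply(seq_along(k_values), function(i) {
    k1 <- site_keys(runs[[i]]$sites)
    shared <- length(intersect(k1, k2))
    sens <- if (length(k2) > 0L) shared / length(k2) else NA_real_
    spec <- if (length(k1) > 0L) shared / length(k1) else NA_real_
    hm <- if (!is.na(sens) && !is.na(spec) && (sens + spec) > 0)
      2 * sens * spec / (sens + spec) else NA_real_
    data.frame(k = k_values[i], n_method1 = length(k1),
               n_method2 = length(k2), n_shared = shared,
               sensitivity = sens, specificity = spec,
               harmonic_mean = hm)
  })
  do.call(rbind, rows)
}

#' Select the mismatch budget from a calibration grid
#'
#' Picks the k maximizing the harmonic mean of sensitivity and
#' specificity (the operationalization of "best combination of
#' sensitivity and specificity"); ties break toward the smaller k.
#' Degenerate rows are skipped; an all-degenerate grid is an error. The
#' full table remains the primary output so alternative criteria can be
#' applied.
#'
#' @param results data.frame from [run_grid()].
#' @return the selected k (integer scalar).
#' @export
select_k <- function(results) {
  ok <- !is.na(results$sensitivity) & !is.na(results$specificity)
  r <- results[ok, , drop = FALSE]
  if (nrow(r) == 0L) stopf("all calibration rows degenerate; cannot select k")
  hm <- ifelse(r$sensitivity + r$specificity > 0,
               2 * r$sensitivity * r$specificity /
                 (r$sensitivity + r$specificity), 0)
  r$k[which.max(hm)]  # which.max takes the first (smallest k) on ties
}
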