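#' Default pipeline configuration
#'
#' All stage parameters of the end-to-end synthetic study in one list:
#' genome layout, planted events, sequencing, mapping budget and caller
#' thresholds. Any element can be overridden via `...`.
#'
#' @param ... named overrides of the defaults.
#' @return named list (a run config).
#' @export
default_config <- function(...) {
  cfg <- list(
    genome_length = 30000L, n_genes = 8L, both_strands = TRUE,
    n_edits = 200L, sre_fraction = 0.4, cluster_spec = NULL,
    n_snps = 10L, n_snp_overlap = 0L,
    depth = 50, read_length = 100L, error_rate = 0.005,
    antisense_ratio = 0.5, background_fraction = 0.1,
    dna_depth = 30,
    k = 7L, c_min = 5L, f_min = 0.1, p_max = 0.05,
    caller_error_rate = 0.01,
    snp_c_min = 10L, snp_f_min = 0.1,
    seed = 1L, out_dir = NULL
  )
  over <- list(...)
  unknown <- setdiff(names(over), names(cfg))
  if (length(unknown) > 0L)
    stopf("unknown config field(s): %s", paste(unknown, collapse = ", "))
  cfg[names(over)] <- over
  cfg
}

#' Score called sites against the planted ground truth
#'
#' Sites and truth events are keyed by (position, strand group,
#' substitution). Recall is the fraction of planted events recovered;
#' precision the fraction of calls that are planted events. SRE-pair
#' recall is computed over planted mirrored positions.
#'
#' @param sites called site table.
#' @param truth `ground_truth`.
#' @param sre_pairs optional [pair_sre()] output for SRE-pair recall.
#' @return named list: `recall`, `precision`, `n_called`, `n_true`, and
#'   when `sre_pairs` is given `sre_recall`, `n_sre_true`.
#' @export
evaluate_against_truth <- function(sites, truth, sre_pairs = NULL) {
  tkey <- paste(truth$edits$position, truth$edits$strand_group,
                truth$edits$rna_ref, truth$edits$rna_alt, sep = ":")
  ckey <- site_keys(sites)
  out <- list(recall = mean(tkey %in% ckey),
              precision = if (length(ckey) > 0L) mean(ckey %in% tkey)
                          else NA_real_,
              n_called = length(ckey), n_true = length(tkey))
  if (!is.null(sre_pairs)) {
    sre_true <- unique(truth$edits$position[truth$edits$is_sre])
    out$sre_recall <- if (length(sre_true) > 0L)
      mean(sre_true %in% sre_pairs$position) else NA_real_
    out$n_sre_true <- length(sre_true)
  }
  out
}

#' Figure-style summary tables for an annotated site set
#'
#' Substitution-type percentages per strand group, frequency-bin
#' histogram, and the distribution of sites across genomic regions
#' (CDS / intron / tRNA / rRNA / intergenic) split by orientation class.
#' Percentages in each marginal sum to 100 (up to rounding) per strand.
#'
#' @param annotated annotated site table ([annotate_sites()]).
#' @return list with `types`, `type_percent`, `freq_bins`, `regions`.
#' @export
summarize_sites <- function(annotated) {
  tf <- type_frequency_summary(annotated)
  pct <- tf$types
  for (sg in c("F", "R")) {
    tot <- sum(pct[[sg]])
    pct[[sg]] <- if (tot > 0L) 100 * pct[[sg]] / tot else 0
  }
  reg_levels <- c("CDS", "intron", "tRNA", "rRNA", "intergenic")
  ori_levels <- c("sense", "antisense", "forward", "reverse")
  regions <- as.data.frame(table(
    region = factor(annotated$region, levels = reg_levels),
    orientation = factor(annotated$orientation, levels = ori_levels)),
    stringsAsFactors = FALSE)
  names(regions)[3] <- "count"
  regions <- regions[regions$count > 0L | (
    (regions$region == "intergenic") ==
      (regions$orientation %in% c("forward", "reverse"))), ]
  rownames(regions) <- NULL
  list(types = tf$types, type_percent = pct, freq_bins = tf$freq_bins,
       regions = regions)
}

#' Run the end-to-end synthetic study
#'
#' Simulate a genome with planted editing events, SRE pairs and SNPs;
#' simulate strand-specific RNA reads and genomic DNA reads; map with
#' the configured mismatch budget; split by strand and pile up; call
#' editing sites per strand group; call and exclude DNA SNPs; pair SRE
#' events; annotate; summarize; and score everything against the ground
#' truth. Stage-by-stage record counts are collected in `log` so the
#' narrative (reads mapped, sites called, sites excluded) is
#' reproducible. With `out_dir` set, all tables plus the config are
#' written as TSV/JSON next to each other.
#'
#' @param config list from [default_config()].
#' @return list with `truth`, `alignments` counts, `sites` (kept),
#'   `sites_excluded`, `sre_pairs`, `annotated`, `summary`, `metrics`,
#'   `snps`, `log`, `config`.
#' @export
run_pipeline <- function(config = default_config()) {
  cfg <- config
  need <- c("genome_length", "n_genes", "n_edits", "depth", "read_length",
            "k", "seed")
  present <- names(cfg)[!vapply(cfg, is.null, logical(1))]
  miss <- setdiff(need, present)
  if (length(miss) > 0L)
    stopf("config missing field(s): %s", paste(miss, collapse = ", "))
  log <- list()
  sim <- generate_genome(cfg$genome_length, cfg$n_genes,
                         both_strands = cfg$both_strands, seed = cfg$seed,
                         read_length = cfg$read_length)
  truth <- plant_events(sim$genome, sim$models, cfg$n_edits,
                        sre_fraction = cfg$sre_fraction,
                        cluster_spec = cfg$cluster_spec,
                        n_snps = cfg$n_snps,
                        n_snp_overlap = cfg$n_snp_overlap,
                        seed = cfg$seed + 1L)
  rna <- simulate_reads(sim$genome, sim$models, truth, depth = cfg$depth,
                        read_length = cfg$read_length,
                        error_rate = cfg$error_rate,
                        antisense_ratio = cfg$antisense_ratio,
                        background_fraction = cfg$background_fraction,
                        seed = cfg$seed + 2L)
  log$n_reads <- nrow(rna$reads)
  aln <- map_reads(rna$reads, sim$genome, max_mismatch = cfg$k)
  groups <- split_by_strand(aln)
  log$n_mapped <- sum(aln$mapped)
  log$n_forward <- unname(groups$counts["F"])
  log$n_reverse <- unname(groups$counts["R"])
  pileup <- build_pileup(aln, sim$genome)
  sites_raw <- call_editing_sites(pileup, sim$genome, c_min = cfg$c_min,
                                  f_min = cfg$f_min, p_max = cfg$p_max,
                                  error_rate = cfg$caller_error_rate,
                                  sample = "pooled")
  log$n_sites_raw <- nrow(sites_raw)
  snps <- NULL
  if (!is.null(cfg$dna_depth) && cfg$dna_depth > 0) {
    dna <- simulate_dna_reads(sim$genome, truth, depth = cfg$dna_depth,
                              read_length = cfg$read_length,
                              error_rate = cfg$error_rate,
                              seed = cfg$seed + 3L)
    dna_aln <- map_reads(dna, sim$genome, max_mismatch = 3L)
    dna_pu <- build_pileup_unstranded(dna_aln, sim$genome)
    snps <- call_snps(dna_pu, sim$genome, c_min = cfg$snp_c_min,
                      f_min = cfg$snp_f_min)
    log$n_snps_hq <- sum(snps$high_quality)
  } else {
    snps <- data.frame(position = truth$snps$position,
                       ref = truth$snps$ref, alt = truth$snps$alt,
                       depth = rep(NA_integer_, nrow(truth$snps)),
                       allele_frequency = truth$snps$allele_frequency,
                       is_indel = truth$snps$is_indel,
                       high_quality = rep(TRUE, nrow(truth$snps)),
                       stringsAsFactors = FALSE)
    log$n_snps_hq <- nrow(snps)
  }
  excl <- exclude_snp_overlaps(sites_raw, snps)
  sites <- excl$kept
  log$n_sites_kept <- nrow(sites)
  log$n_sites_excluded <- nrow(excl$excluded)
  sre_pairs <- pair_sre(sites[sites$strand_group == "F", ],
                        sites[sites$strand_group == "R", ])
  log$n_sre_pairs <- nrow(sre_pairs)
  annotated <- annotate_sites(sites, sim$genome, sim$models)
  summary <- summarize_sites(annotated)
  metrics <- evaluate_against_truth(sites, truth, sre_pairs)
  res <- list(genome = sim$genome, models = sim$models, truth = truth,
              sites = sites, sites_excluded = excl$excluded,
              snps = snps, sre_pairs = sre_pairs, annotated = annotated,
              summary = summary, metrics = metrics, log = log,
              config = cfg)
  if (!is.null(cfg$out_dir)) write_pipeline_outputs(res, cfg$out_dir)
  res
}

write_pipeline_outputs <- function(res, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  p <- function(f) file.path(out_dir, f)
  write_fasta(res$genome, p("genome.fasta"))
  write_gff(res$models, p("genes.gff3"))
  write_site_table(res$sites, p("sites.tsv"))
  write_site_table(res$sites_excluded, p("sites_excluded.tsv"))
  wt <- function(d, f) write.table(d, p(f), sep = "\t", quote = FALSE,
                                   row.names = FALSE)
  wt(res$sre_pairs, "sre_pairs.tsv")
  wt(res$annotated, "sites_annotated.tsv")
  wt(res$snps, "snps.tsv")
  wt(res$summary$types, "summary_types.tsv")
  wt(res$summary$freq_bins, "summary_freq_bins.tsv")
  wt(res$summary$regions, "summary_regions.tsv")
  cfg <- res$config
  cfg$cluster_spec <- if (is.null(cfg$cluster_spec)) NULL
                      else as.list(cfg$cluster_spec)
  jsonlite::write_json(cfg[!vapply(cfg, is.null, logical(1))],
                       p("config.json"), auto_unbox = TRUE, digits = NA)
  jsonlite::write_json(c(res$log, res$metrics), p("run_log.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(out_dir)
}
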