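# shared read-construction core: windows are genome-forward strings; edits
# and SNPs are applied per molecule, then uniform substitution errors.
build_molecules <- function(gseq, starts, strand_group, read_length,
                            events, snps, error_rate) {
  n <- length(starts)
  if (n == 0L) return(character(0))
  seqs <- substring(gseq, starts, starts + read_length - 1L)
  chars <- matrix(unlist(strsplit(seqs, "", fixed = TRUE)), nrow = n,
                  byrow = TRUE)
  # planted editing events: genome-space alt with prob editing_frequency,
  # only on reads of the event's strand group
  if (!is.null(events) && nrow(events) > 0L) {
    galt <- rna_to_genome_space(events$rna_alt, events$strand_group)
    for (e in seq_len(nrow(events))) {
      p <- events$position[e]
      hit <- which(strand_group == events$strand_group[e] &
                     starts <= p & starts + read_length - 1L >= p)
      if (length(hit) == 0L) next
      edited <- hit[runif(length(hit)) < events$editing_frequency[e]]
      chars[cbind(edited, p - starts[edited] + 1L)] <- galt[e]
    }
  }
  # DNA SNPs are transcribed into RNA of both strands at allele frequency
  if (!is.null(snps) && nrow(snps) > 0L) {
    subs <- snps[!snps$is_indel, , drop = FALSE]
    for (s in seq_len(nrow(subs))) {
      p <- subs$position[s]
      hit <- which(starts <= p & starts + read_length - 1L >= p)
      if (length(hit) == 0L) next
      var <- hit[runif(length(hit)) < subs$allele_frequency[s]]
      chars[cbind(var, p - starts[var] + 1L)] <- subs$alt[s]
    }
  }
  if (error_rate > 0) {
    err <- which(matrix(runif(length(chars)) < error_rate, nrow = n),
                 arr.ind = TRUE)
    if (nrow(err) > 0L) {
      cur <- chars[err]
      repl <- vapply(cur, function(b) sample(setdiff(DNA_BASES, b), 1L),
                     character(1), USE.NAMES = FALSE)
      chars[err] <- repl
    }
  }
  apply(chars, 1L, paste, collapse = "")
}

#' Simulate strand-specific RNA-Seq reads with a truth alignment
#'
#' Single-end reads under an FR strand-specific protocol: the read
#' sequence is the transcript strand, so a read from a reverse-strand
#' transcript is the reverse complement of the forward reference window
#' and belongs to strand group R (SAM flag 16). Each gene produces sense
#' reads to the target `depth` and antisense reads (pervasive antisense
#' transcription, the substrate of symmetric editing) at
#' `antisense_ratio` times that depth; intergenic background reads on
#' both strands make up `background_fraction` of the total. Reads
#' overlapping a planted edit on their strand group carry the edited base
#' with probability equal to the site's editing frequency; DNA SNP
#' alleles appear in reads of both groups at their allele frequency;
#' uniform substitution errors are added at `error_rate`. Reads never
#' cross the circular origin (the generator keeps genes away from it).
#'
#' @param genome named character vector (one contig).
#' @param models `gene_models` annotation.
#' @param truth `ground_truth` from [plant_events()] (or a compatible
#'   list with `edits` and `snps`).
#' @param depth target sense coverage over gene bodies (x).
#' @param read_length read length (bp).
#' @param error_rate per-base substitution error rate, in `[0, 0.05]`.
#' @param protocol strand protocol; only "FR" is supported.
#' @param antisense_ratio antisense transcription level relative to sense.
#' @param background_fraction fraction of all reads drawn uniformly from
#'   the whole genome on random strands.
#' @param seed RNG seed; identical seeds give identical output.
#' @return list with `reads` (data.frame `id`, `seq`, `qual`; `seq` in
#'   sequenced/transcript orientation) and `truth_sam` (alignment
#'   data.frame: `read_id`, `contig`, `position`, `strand_group`, `seq`
#'   in genome-forward orientation, `mapped`).
#' @export
simulate_reads <- function(genome, models, truth, depth = 50,
                           read_length = 100L, error_rate = 0.01,
                           protocol = "FR", antisense_ratio = 0.5,
                           background_fraction = 0.1, seed = 1L) {
  if (!identical(protocol, "FR"))
    stopf("only the FR strand protocol is supported")
  if (depth < 1) stopf("depth must be >= 1")
  if (error_rate < 0 || error_rate > 0.05)
    stopf("error_rate must be in [0, 0.05]")
  gseq <- unname(genome[[1]])
  glen <- nchar(gseq)
  if (read_length > glen) stopf("read_length exceeds genome length")
  set.seed(seed)
  contig <- if (!is.null(names(genome))) names(genome)[1] else "contig"
  genes <- unique(models$features[models$features$type == "gene",
                                  c("start", "end", "strand", "gene_id")])
  starts <- integer(0); sg <- character(0)
  for (i in seq_len(nrow(genes))) {
    span <- genes$end[i] - genes$start[i] + 1L
    lo <- max(1L, genes$start[i] - read_length + 1L)
    hi <- min(glen - read_length + 1L, genes$end[i])
    n_sense <- ceiling(depth * (hi - lo + 1L) / read_length)
    n_anti <- ceiling(antisense_ratio * n_sense)
    s_sense <- sample(lo:hi, n_sense, replace = TRUE)
    s_anti <- sample(lo:hi, n_anti, replace = TRUE)
    sense_grp <- if (genes$strand[i] == "+") "F" else "R"
    anti_grp <- if (sense_grp == "F") "R" else "F"
    starts <- c(starts, s_sense, s_anti)
    sg <- c(sg, rep(sense_grp, n_sense), rep(anti_grp, n_anti))
  }
  n_tx <- length(starts)
  n_bg <- ceiling(n_tx * background_fraction / (1 - background_fraction))
  if (n_bg > 0L) {
    starts <- c(starts, sample(glen - read_length + 1L, n_bg,
                               replace = TRUE))
    sg <- c(sg, sample(c("F", "R"), n_bg, replace = TRUE))
  }
  mol <- build_molecules(gseq, starts, sg, read_length,
                         truth$edits, truth$snps, error_rate)
  ids <- sprintf("sim%06d", seq_along(mol))
  # FASTQ sequence is the transcript strand; truth SAM stores the
  # genome-forward sequence with the orientation bit
  fastq_seq <- ifelse(sg == "R", dna_revcomp(mol), mol)
  list(
    reads = data.frame(id = ids, seq = fastq_seq,
                       qual = strrep("I", read_length),
                       stringsAsFactors = FALSE),
    truth_sam = data.frame(read_id = ids, contig = contig,
                           position = starts, strand_group = sg,
                           seq = mol, mapped = TRUE,
                           stringsAsFactors = FALSE)
  )
}

#' Simulate whole-genome DNA reads for SNP calling
#'
#' Strand-agnostic genomic reads at uniform coverage. SNP alleles appear
#' at their allele frequency; editing events do not (they are
#' RNA-level). Used as the internal route into [call_snps()].
#'
#' @inheritParams simulate_reads
#' @return data.frame of reads (`id`, `seq`, `qual`), sequences in the
#'   sequenced orientation (random strand).
#' @export
simulate_dna_reads <- function(genome, truth, depth = 30,
                               read_length = 100L, error_rate = 0.01,
                               seed = 1L) {
  gseq <- unname(genome[[1]])
  glen <- nchar(gseq)
  if (read_length > glen) stopf("read_length exceeds genome length")
  set.seed(seed)
  n <- ceiling(depth * glen / read_length)
  starts <- sample(glen - read_length + 1L, n, replace = TRUE)
  sg <- sample(c("F", "R"), n, replace = TRUE)
  mol <- build_molecules(gseq, starts, sg, read_length,
                         NULL, truth$snps, error_rate)
  data.frame(id = sprintf("dna%06d", seq_len(n)),
             seq = ifelse(sg == "R", dna_revcomp(mol), mol),
             qual = strrep("I", read_length), stringsAsFactors = FALSE)
}
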