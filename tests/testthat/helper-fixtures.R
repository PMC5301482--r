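# small fixture builders shared by the suite

# a minimal single-gene genome: one forward CDS embedded in random sequence
tiny_genome <- function(seed = 1L, len = 6000L, n_genes = 2L,
                        both = TRUE) {
  generate_genome(len, n_genes, both_strands = both, seed = seed,
                  read_length = 100L)
}

# hand-built gene models from coordinate triples
models_from <- function(...) {
  rows <- list(...)
  gene_models(do.call(rbind, lapply(rows, function(r)
    data.frame(seqid = "m", type = r[[1]], start = as.integer(r[[2]]),
               end = as.integer(r[[3]]), strand = r[[4]],
               gene_id = r[[5]], stringsAsFactors = FALSE))))
}

# one-row site table
site_row <- function(position, strand_group, rna_ref, rna_alt,
                     depth = 20L, alt_count = 10L, p_value = 1e-6,
                     sample = "s1", contig = "m") {
  data.frame(contig = contig, position = as.integer(position),
             strand_group = strand_group, rna_ref = rna_ref,
             rna_alt = rna_alt, depth = as.integer(depth),
             alt_count = as.integer(alt_count),
             frequency = alt_count / depth, p_value = p_value,
             sample = sample, stringsAsFactors = FALSE)
}

# pileup row in the build_pileup() layout
pileup_row <- function(position, strand_group, A = 0L, C = 0L, G = 0L,
                       T = 0L) {
  data.frame(position = as.integer(position), strand_group = strand_group,
             A = as.integer(A), C = as.integer(C), G = as.integer(G),
             T = as.integer(T), depth = as.integer(A + C + G + T),
             stringsAsFactors = FALSE)
}

# three synthetic species derived from one ancestral CDS, with known
# ancestral->derived offset maps (2% divergence, occasional codon indels)
synth_species <- function(seed = 1) {
  set.seed(seed)
  n_codon <- 60
  stops <- c("TAA", "TAG", "TGA")
  sense <- setdiff(names(Biostrings::GENETIC_CODE), stops)
  anc <- paste0("ATG", paste(sample(sense, n_codon - 2, replace = TRUE),
                             collapse = ""), "TAA")
  sp <- list(A = list(seq = anc, map = seq_len(nchar(anc))))
  for (nm in c("B", "C")) {
    m <- mutate_cds(anc, divergence = 0.02, codon_indel_rate = 0.02,
                    seed = seed + match(nm, c("B", "C")))
    sp[[nm]] <- list(seq = m$seq, map = m$offset_map)
  }
  sp
}
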