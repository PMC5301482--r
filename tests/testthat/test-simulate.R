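test_that("genome generation is deterministic and capacity-checked", {
  g1 <- generate_genome(20000, 6, TRUE, seed = 1)
  g2 <- generate_genome(20000, 6, TRUE, seed = 1)
  expect_identical(g1$genome, g2$genome)
  expect_identical(g1$models$features, g2$models$features)
  g3 <- generate_genome(20000, 6, TRUE, seed = 2)
  expect_false(identical(g1$genome, g3$genome))

  expect_error(generate_genome(5000, 500, TRUE, seed = 1), "cannot fit")
  expect_error(generate_genome(4000, 2, TRUE, seed = 1), ">= 5000")
})

test_that("every generated CDS translates cleanly (translate-and-scan oracle)", {
  g <- generate_genome(24000, 7, TRUE, seed = 5)
  for (gid in names(g$models$cds)) {
    tr <- cds_transcript(unname(g$genome[[1]]), g$models, gid)
    expect_equal(nchar(tr$seq) %% 3L, 0L)
    aa <- as.character(Biostrings::translate(Biostrings::DNAString(tr$seq)))
    expect_equal(substr(aa, 1, 1), "M")
    expect_equal(substr(aa, nchar(aa), nchar(aa)), "*")
    # no internal stop
    expect_false(grepl("\\*", substr(aa, 1, nchar(aa) - 1L)))
  }
  # layout constraints: genes off the origin, gaps >= 2 read lengths
  fe <- g$models$features[g$models$features$type == "gene", ]
  fe <- fe[order(fe$start), ]
  expect_true(min(fe$start) > 100L)
  expect_true(max(fe$end) <= 24000L - 100L)
  expect_true(all(diff(fe$start)[] >= 0))
  expect_true(all(fe$start[-1] - fe$end[-nrow(fe)] - 1L >= 200L))
  # both strands used
  expect_setequal(unique(fe$strand), c("+", "-"))
})

test_that("planted events respect SRE pairing, clustering and counts", {
  g <- tiny_genome(seed = 2, len = 20000, n_genes = 6)
  tr <- plant_events(g$genome, g$models, 40, sre_fraction = 0.5, seed = 3)
  sre <- tr$edits[tr$edits$is_sre, ]
  expect_equal(length(unique(sre$position)), 20L)
  expect_equal(nrow(tr$edits), 20L + 40L)  # 20 plain + 20 mirrored pairs
  # exact mirrors: F C->U at p implies R G->A at p (and vice versa)
  for (p in unique(sre$position)) {
    pair <- sre[sre$position == p, ]
    expect_setequal(pair$strand_group, c("F", "R"))
    f <- pair[pair$strand_group == "F", ]
    r <- pair[pair$strand_group == "R", ]
    expect_identical(r$rna_ref, rna_complement(f$rna_ref))
    expect_identical(r$rna_alt, rna_complement(f$rna_alt))
    expect_true(all(pair$rna_ref %in% c("C", "G")))
  }
  # planted reference bases match the genome
  gseq <- unname(g$genome[[1]])
  expect_identical(
    substring(gseq, tr$edits$position, tr$edits$position),
    rna_to_genome_space(tr$edits$rna_ref, tr$edits$strand_group))

  # clusters: demanded window materializes
  trc <- plant_events(g$genome, g$models, 30, sre_fraction = 0,
                      cluster_spec = list(n_edits = 5, window = 90),
                      seed = 4)
  pos <- sort(trc$edits$position)
  inwin <- vapply(pos, function(p) sum(pos >= p & pos <= p + 89L),
                  integer(1))
  expect_gte(max(inwin), 5L)

  # SNPs disjoint from edits unless overlap requested
  trs <- plant_events(g$genome, g$models, 30, n_snps = 10, seed = 5)
  expect_length(intersect(trs$snps$position, trs$edits$position), 0L)
  tro <- plant_events(g$genome, g$models, 30, n_snps = 5,
                      n_snp_overlap = 2, seed = 6)
  expect_length(intersect(tro$snps$position, tro$edits$position), 2L)

  expect_error(plant_events(g$genome, g$models, 1e6, seed = 1),
               "eligible positions")
})

test_that("simulated reads carry planted alleles per strand and are deterministic", {
  g <- tiny_genome(seed = 11, len = 8000, n_genes = 2)
  gseq <- unname(g$genome[[1]])
  tr <- plant_events(g$genome, g$models, 10, sre_fraction = 0,
                     freq_dist = function(n) rep(1.0, n), seed = 2)
  rna <- simulate_reads(g$genome, g$models, tr, depth = 50,
                        read_length = 100, error_rate = 0, seed = 3)
  rna2 <- simulate_reads(g$genome, g$models, tr, depth = 50,
                         read_length = 100, error_rate = 0, seed = 3)
  expect_identical(rna$reads, rna2$reads)

  ts <- rna$truth_sam
  # frequency-1 edits: every same-group truth read covering the site
  # carries the genome-space alt
  for (i in seq_len(nrow(tr$edits))) {
    e <- tr$edits[i, ]
    cov <- ts[ts$strand_group == e$strand_group &
                ts$position <= e$position &
                ts$position + 99L >= e$position, ]
    expect_gt(nrow(cov), 0L)
    at <- substring(cov$seq, e$position - cov$position + 1L,
                    e$position - cov$position + 1L)
    expect_true(all(at == rna_to_genome_space(e$rna_alt, e$strand_group)))
  }
  # a reverse-group read's FASTQ sequence is the reverse complement of
  # its genome-space truth sequence (hand-checked orientation law)
  rrow <- which(ts$strand_group == "R")[1]
  fq <- rna$reads$seq[match(ts$read_id[rrow], rna$reads$id)]
  expect_identical(fq, dna_revcomp(ts$seq[rrow]))
  # forward reads are written as-is
  frow <- which(ts$strand_group == "F")[1]
  expect_identical(rna$reads$seq[match(ts$read_id[frow], rna$reads$id)],
                   ts$seq[frow])
  # no read crosses the circular origin
  expect_true(all(ts$position >= 1L &
                    ts$position + 99L <= nchar(gseq)))

  expect_error(simulate_reads(g$genome, g$models, tr, depth = 5,
                              read_length = 9000, seed = 1),
               "read_length")
  expect_error(simulate_reads(g$genome, g$models, tr, depth = 5,
                              error_rate = 0.2, seed = 1), "error_rate")
})

test_that("empirical alt fraction tracks the planted editing frequency", {
  g <- tiny_genome(seed = 21, len = 8000, n_genes = 2)
  tr <- plant_events(g$genome, g$models, 12, sre_fraction = 0,
                     freq_dist = function(n) runif(n, 0.3, 0.9), seed = 7)
  rna <- simulate_reads(g$genome, g$models, tr, depth = 200,
                        read_length = 100, error_rate = 0, seed = 8)
  pu <- build_pileup(rna$truth_sam, g$genome)
  for (i in seq_len(nrow(tr$edits))) {
    e <- tr$edits[i, ]
    col <- pu[pu$position == e$position &
                pu$strand_group == e$strand_group, ]
    alt_base <- rna_to_genome_space(e$rna_alt, e$strand_group)
    frac <- col[[alt_base]] / col$depth
    tol <- 3 * sqrt(e$editing_frequency * (1 - e$editing_frequency) /
                      col$depth)
    expect_lt(abs(frac - e$editing_frequency), tol + 1e-9)
  }
})
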