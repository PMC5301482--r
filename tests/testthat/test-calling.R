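test_that("pileup tallies genome-space bases per strand column", {
  genome <- c(m = strrep("GATTACAGATTACA", 10))
  one <- data.frame(read_id = "r", contig = "m", position = 10L,
                    strand_group = "F", seq = "ACGT", mapped = TRUE,
                    stringsAsFactors = FALSE)
  pu <- build_pileup(one, genome)
  expect_equal(pu$position, 10:13)
  expect_true(all(pu$depth == 1L))
  expect_equal(pu$strand_group, rep("F", 4))

  two <- rbind(within(one, seq <- "ACCT"),
               within(one, { seq <- "ACTT"; read_id <- "r2" }))
  pu2 <- build_pileup(two, genome)
  col12 <- pu2[pu2$position == 12L, ]
  expect_equal(col12$C, 1L)
  expect_equal(col12$T, 1L)
  expect_equal(col12$depth, 2L)

  # out-of-bounds alignment errors
  oob <- within(one, position <- 139L)
  expect_error(build_pileup(oob, genome), "bounds")

  # N contributes nothing
  withn <- within(one, seq <- "ANGT")
  pun <- build_pileup(withn, genome)
  expect_false(11L %in% pun$position)
})

test_that("pileup depths equal an interval-stabbing oracle on random fixtures", {
  g <- tiny_genome(seed = 31, len = 6000, n_genes = 2)
  tr <- plant_events(g$genome, g$models, 10, seed = 2)
  rna <- simulate_reads(g$genome, g$models, tr, depth = 12,
                        read_length = 90, error_rate = 0.01, seed = 3)
  ts <- rna$truth_sam
  pu <- build_pileup(ts, g$genome)
  set.seed(44)
  probe <- sample(pu$position, 30)
  for (p in probe) {
    for (sg in c("F", "R")) {
      d <- pu$depth[pu$position == p & pu$strand_group == sg]
      d <- if (length(d) == 0L) 0L else d
      expect_equal(d, stab_oracle(ts$position[ts$strand_group == sg],
                                  90L, p))
    }
  }
})

test_that("editing caller applies thresholds, converts strands, excludes multi-type", {
  genome <- c(m = paste0(strrep("A", 9), "C", strrep("A", 10)))
  # ref C at position 10
  hi <- pileup_row(10, "F", C = 10, T = 90)
  s <- call_editing_sites(hi, genome, error_rate = 0.01)
  expect_equal(nrow(s), 1L)
  expect_equal(s$rna_ref, "C"); expect_equal(s$rna_alt, "U")
  expect_equal(s$frequency, 0.9)
  # p-value matches the independent exact-summation oracle
  expect_lt(abs(s$p_value - binom_tail_oracle(90, 100, 0.01 / 3)), 1e-12)
  expect_lte(s$p_value, 0.05)

  # coverage threshold: depth 4 never called, depth 5 can be
  expect_equal(nrow(call_editing_sites(pileup_row(10, "F", T = 4),
                                       genome)), 0L)
  expect_equal(nrow(call_editing_sites(pileup_row(10, "F", T = 5),
                                       genome)), 1L)

  # frequency threshold: 0.05 fails, exactly 0.1 passes
  expect_equal(nrow(call_editing_sites(
    pileup_row(10, "F", C = 18, T = 1, A = 1), genome)), 0L)
  ten <- call_editing_sites(pileup_row(10, "F", C = 9, T = 1), genome)
  expect_equal(ten$frequency, 0.1)
  expect_equal(nrow(ten), 1L)

  # multi-type exclusion discards the whole column
  multi <- call_editing_sites(pileup_row(10, "F", C = 5, T = 8, A = 7),
                              genome)
  expect_equal(nrow(multi), 0L)
  # ...but only on its own strand group: R column at the same position
  both <- rbind(pileup_row(10, "F", C = 5, T = 8, A = 7),
                pileup_row(10, "R", C = 2, T = 18))
  sb <- call_editing_sites(both, genome)
  expect_equal(nrow(sb), 1L)
  expect_equal(sb$strand_group, "R")
  # reverse-group RNA space: genome C->T complements to G->A
  expect_equal(sb$rna_ref, "G"); expect_equal(sb$rna_alt, "A")

  # reference N columns are skipped with a warning
  gn <- c(m = paste0(strrep("A", 9), "N", strrep("A", 10)))
  expect_warning(sn <- call_editing_sites(pileup_row(10, "F", T = 20), gn),
                 "N")
  expect_equal(nrow(sn), 0L)
})

test_that("caller p-values match the exact-summation oracle over a depth grid", {
  set.seed(99)
  genome <- c(m = paste0("C", strrep("A", 600)))
  for (er in c(0.003, 0.01, 0.05)) {
    depths <- sample(5:500, 40)
    for (d in depths) {
      alt <- sample.int(d, 1)
      pu <- pileup_row(1, "F", C = d - alt, T = alt)
      s <- call_editing_sites(pu, genome, f_min = 0, p_max = 1,
                              error_rate = er)
      if (nrow(s) == 1L) {
        expect_lt(abs(s$p_value - binom_tail_oracle(alt, d, er / 3)),
                  1e-12)
      }
    }
  }
})

test_that("SNP caller and exclusion behave per thresholds and indel spans", {
  genome <- c(m = paste0(strrep("A", 9), "C", strrep("A", 10)))
  pu <- data.frame(position = 10L, A = 0L, C = 20L, G = 0L, T = 20L,
                   depth = 40L)
  snp <- call_snps(pu, genome)
  expect_equal(nrow(snp), 1L)
  expect_equal(snp$allele_frequency, 0.5)
  expect_true(snp$high_quality)

  low <- data.frame(position = 10L, A = 0L, C = 0L, G = 0L, T = 9L,
                    depth = 9L)
  s2 <- call_snps(low, genome)
  expect_false(s2$high_quality)  # coverage < 10

  # VCF-derived sites: indel span exclusion
  p <- withr::local_tempfile(fileext = ".vcf")
  writeLines(c("#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO",
               "m\t120\t.\tC\tT\t.\t.\tDP=40;AF=0.5",
               "m\t5\t.\tATT\tA\t.\t.\t."), p)
  snps <- snp_sites_from_vcf(read_vcf_min(p))
  expect_true(all(snps$high_quality))
  expect_true(snps$is_indel[snps$position == 5L])

  sites <- rbind(site_row(120, "F", "C", "U"),
                 site_row(121, "F", "C", "U"),
                 site_row(6, "R", "G", "A"),
                 site_row(8, "F", "C", "U"))
  ex <- exclude_snp_overlaps(sites, snps)
  expect_equal(sort(ex$excluded$position), c(6L, 120L))
  expect_equal(sort(ex$kept$position), c(8L, 121L))
  expect_equal(nrow(ex$kept) + nrow(ex$excluded), nrow(sites))
})

test_that("consensus caller takes strict majorities and matches truth at high frequency", {
  genome <- c(m = paste0(strrep("A", 9), "C", strrep("A", 10)))
  maj <- consensus_sites(pileup_row(10, "F", C = 3, T = 7), genome)
  expect_equal(nrow(maj), 1L)
  expect_equal(maj$rna_alt, "U")
  expect_true(is.na(maj$p_value))
  tie <- consensus_sites(pileup_row(10, "F", C = 5, T = 5), genome)
  expect_equal(nrow(tie), 0L)

  # with error 0 and planted frequencies >= 0.8, the consensus set equals
  # the planted set restricted to covered depth
  g <- tiny_genome(seed = 41, len = 8000, n_genes = 2)
  tr <- plant_events(g$genome, g$models, 15, sre_fraction = 0.4,
                     freq_dist = function(n) runif(n, 0.8, 1), seed = 2)
  rna <- simulate_reads(g$genome, g$models, tr, depth = 40,
                        read_length = 100, error_rate = 0, seed = 3)
  pu <- build_pileup(rna$truth_sam, g$genome)
  cs <- consensus_sites(pu, g$genome, c_min = 5)
  tkey <- paste(tr$edits$position, tr$edits$strand_group,
                tr$edits$rna_ref, tr$edits$rna_alt, sep = ":")
  ckey <- paste(cs$position, cs$strand_group, cs$rna_ref, cs$rna_alt,
                sep = ":")
  expect_setequal(ckey, tkey)
})

test_that("pooling concatenates samples and is order-independent downstream", {
  mk <- function(n, sample_seed) {
    set.seed(sample_seed)
    data.frame(read_id = sprintf("r%d_%d", sample_seed, seq_len(n)),
               contig = "m", position = sample(50, n, replace = TRUE),
               strand_group = sample(c("F", "R"), n, replace = TRUE),
               seq = strrep("A", 10), mapped = TRUE,
               stringsAsFactors = FALSE)
  }
  a <- mk(3, 1); b <- mk(4, 2); c3 <- mk(5, 3)
  pool <- pool_samples(leaf = a, flower = b, root = c3)
  expect_equal(nrow(pool), 12L)
  expect_setequal(unique(pool$sample), c("leaf", "flower", "root"))

  genome <- c(m = strrep("C", 60))
  p1 <- build_pileup(pool_samples(leaf = a, flower = b, root = c3), genome)
  p2 <- build_pileup(pool_samples(root = c3, leaf = a, flower = b), genome)
  expect_equal(p1, p2)

  expect_equal(nrow(pool_samples(x = a, y = a[0, ])), 3L)
  bad <- a; bad$contig <- "other"
  expect_error(pool_samples(x = a, y = bad), "different references")
})

test_that("reverse-only transcription with mirrored editing yields only G-to-A calls in group R", {
  # all coverage on the reverse strand group; planted events manifest as
  # genome-space C->T, i.e. G->A in the reverse transcripts' own space
  set.seed(55)
  gseq <- paste(sample(c("A", "C", "G", "T"), 4000, replace = TRUE),
                collapse = "")
  genome <- c(m = gseq)
  cpos <- which(strsplit(gseq, "")[[1]] == "C")
  cpos <- cpos[cpos > 300 & cpos < 3700][1:12]
  edits <- data.frame(position = cpos, strand_group = "R",
                      rna_ref = "G", rna_alt = "A",
                      editing_frequency = 0.9, is_sre = FALSE,
                      stringsAsFactors = FALSE)
  starts <- rep(seq(1, 3900, by = 10), each = 2)
  starts <- starts[starts + 99 <= 4000]
  mol <- mitosre:::build_molecules(gseq, starts, rep("R", length(starts)),
                                   100L, edits, NULL, 0)
  aln <- data.frame(read_id = sprintf("r%d", seq_along(mol)), contig = "m",
                    position = starts, strand_group = "R", seq = mol,
                    mapped = TRUE, stringsAsFactors = FALSE)
  pu <- build_pileup(aln, genome)
  sites <- call_editing_sites(pu, genome)
  expect_gt(nrow(sites), 0L)
  expect_true(all(sites$strand_group == "R"))
  expect_true(all(sites$rna_ref == "G" & sites$rna_alt == "A"))
  expect_setequal(sites$position, cpos)

  # mirror fixture: same columns on forward-only coverage give C->U in F
  molF <- mitosre:::build_molecules(gseq, starts, rep("F", length(starts)),
                                    100L,
                                    within(edits, {
                                      strand_group <- "F"
                                      rna_ref <- "C"; rna_alt <- "U"
                                    }), NULL, 0)
  alnF <- data.frame(read_id = sprintf("f%d", seq_along(molF)),
                     contig = "m", position = starts, strand_group = "F",
                     seq = molF, mapped = TRUE, stringsAsFactors = FALSE)
  sitesF <- call_editing_sites(build_pileup(alnF, genome), genome)
  expect_true(all(sitesF$strand_group == "F"))
  expect_true(all(sitesF$rna_ref == "C" & sitesF$rna_alt == "U"))
  expect_setequal(sitesF$position, cpos)
})
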