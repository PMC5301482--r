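test_that("site location follows containment, precedence and orientation rules", {
  mod <- models_from(
    list("gene", 101, 400, "+", "g1"),
    list("CDS", 101, 220, "+", "g1"),
    list("intron", 221, 280, "+", "g1"),
    list("CDS", 281, 400, "+", "g1"),
    list("gene", 600, 700, "-", "t1"),
    list("tRNA", 600, 700, "-", "t1"))
  loc <- locate_site(site_row(150, "F", "C", "U"), mod)
  expect_equal(loc$region, "CDS")
  expect_equal(loc$orientation, "sense")
  # antisense: reverse-group site in a plus-strand CDS
  loc2 <- locate_site(site_row(150, "R", "G", "A"), mod)
  expect_equal(loc2$region, "CDS")
  expect_equal(loc2$orientation, "antisense")
  expect_equal(locate_site(site_row(250, "F", "C", "U"), mod)$region,
               "intron")
  loc3 <- locate_site(site_row(650, "R", "C", "U"), mod)
  expect_equal(loc3$region, "tRNA")
  expect_equal(loc3$orientation, "sense")  # R group, minus-strand gene
  # intergenic sites labelled by strand group
  loc4 <- locate_site(site_row(500, "F", "C", "U"), mod)
  expect_equal(loc4$region, "intergenic")
  expect_equal(loc4$orientation, "forward")
  expect_equal(locate_site(site_row(500, "R", "C", "U"), mod)$orientation,
               "reverse")

  overlapping <- models_from(
    list("gene", 101, 300, "+", "a"), list("CDS", 101, 300, "+", "a"),
    list("gene", 250, 400, "+", "b"), list("CDS", 250, 400, "+", "b"))
  expect_error(locate_site(site_row(260, "F", "C", "U"), overlapping),
               "multiple genes")
})

test_that("locate assigns every (position, strand) to exactly one region", {
  g <- tiny_genome(seed = 51, len = 6000, n_genes = 2)
  set.seed(8)
  for (p in sample(6000, 40)) for (sg in c("F", "R")) {
    loc <- mitosre:::locate_one(p, sg, g$models)
    expect_true(loc$region %in%
                  c("CDS", "intron", "tRNA", "rRNA", "intergenic"))
    expect_length(loc$region, 1L)
  }
})

test_that("codon effects reproduce the genetic-code consequences", {
  # hand-built gene: ACG GCT TAC CAA TCA TAA  (+ strand, starts at 101)
  cds <- "ACGGCTTACCAATCATAA"
  gseq <- paste0(strrep("G", 100), cds, strrep("G", 100))
  genome <- c(m = gseq)
  mod <- models_from(list("gene", 101, 118, "+", "g1"),
                     list("CDS", 101, 118, "+", "g1"))
  # ACG -> AUG at codon 1, position 2: start gain
  cf <- codon_effect(site_row(102, "F", "C", "U"), genome, mod, "g1")
  expect_equal(cf$codon_index, 1L)
  expect_equal(cf$codon_position, 2L)
  expect_equal(cf$alt_codon, "AUG")
  expect_equal(cf$effect, "start_gain")
  # TCA (Ser) -> TTA (Leu): missense
  cf2 <- codon_effect(site_row(114, "F", "C", "U"), genome, mod, "g1")
  expect_equal(cf2$ref_codon, "UCA")
  expect_equal(cf2$alt_codon, "UUA")
  expect_equal(cf2$ref_aa, "S"); expect_equal(cf2$alt_aa, "L")
  expect_equal(cf2$effect, "missense")
  # TAC (Tyr) -> TAT (Tyr): silent
  cf3 <- codon_effect(site_row(109, "F", "C", "U"), genome, mod, "g1")
  expect_equal(cf3$effect, "silent")
  # CAA (Gln) -> TAA (stop): stop gain
  cf4 <- codon_effect(site_row(110, "F", "C", "U"), genome, mod, "g1")
  expect_equal(cf4$alt_codon, "UAA")
  expect_equal(cf4$effect, "stop_gain")
})

test_that("codon effect agrees with a mutate-translate-diff oracle over all codons", {
  codons <- names(Biostrings::GENETIC_CODE)
  pad <- "ATGGGG"  # fixed prefix so the probe codon is codon 3
  for (codon in codons) for (pos in 1:3) {
    if (substr(codon, pos, pos) != "C") next
    cds <- paste0(pad, codon, "TAA")
    cf <- mitosre:::codon_fields(cds, 6L + pos, "U")
    # oracle: mutate the full CDS string, translate both, diff
    mut <- cds
    substr(mut, 6L + pos, 6L + pos) <- "T"
    aa_ref <- as.character(Biostrings::translate(
      Biostrings::DNAString(cds), no.init.codon = TRUE))
    aa_alt <- as.character(Biostrings::translate(
      Biostrings::DNAString(mut), no.init.codon = TRUE))
    d <- which(strsplit(aa_ref, "")[[1]] != strsplit(aa_alt, "")[[1]])
    if (length(d) == 0L) {
      expect_equal(cf$effect, "silent", info = paste(codon, pos))
    } else {
      expect_equal(d, 3L)
      ref_aa <- substr(aa_ref, 3, 3); alt_aa <- substr(aa_alt, 3, 3)
      want <- if (alt_aa == "*") "stop_gain"
              else if (ref_aa == "*") "stop_loss"
              else "missense"
      expect_equal(cf$effect, want, info = paste(codon, pos))
      expect_equal(cf$ref_aa, ref_aa)
      expect_equal(cf$alt_aa, alt_aa)
    }
    expect_equal(3L * (cf$codon_index - 1L) + cf$codon_position, 6L + pos)
  }
})

test_that("annotation names CDS sites gene-offset style and flags start gains", {
  cds <- "ACGGCTTACCAATCATAA"
  gseq <- paste0(strrep("G", 100), cds, strrep("G", 100))
  genome <- c(m = gseq)
  mod <- models_from(list("gene", 101, 118, "+", "g1"),
                     list("CDS", 101, 118, "+", "g1"))
  ann <- annotate_sites(rbind(site_row(102, "F", "C", "U"),
                              site_row(102, "R", "G", "A"),
                              site_row(50, "F", "C", "U")), genome, mod)
  expect_equal(ann$site_name[1], "g1-2")
  expect_equal(ann$effect[1], "start_gain")
  # antisense CDS site carries the offset but no codon consequence
  expect_equal(ann$site_name[2], "g1-2")
  expect_equal(ann$effect[2], "noncoding")
  expect_equal(ann$region[3], "intergenic")
  expect_equal(ann$site_name[3], "m:50:F")
})

test_that("hydrophobicity shift counts membership over affected residues", {
  mk <- function(ref_aa, alt_aa) {
    data.frame(region = "CDS", orientation = "sense", rna_ref = "C",
               rna_alt = "U", ref_aa = ref_aa, alt_aa = alt_aa,
               stringsAsFactors = FALSE)
  }
  # Ser -> Leu: 0% hydrophobic before, 100% after
  expect_equal(unname(hydrophobicity_shift(mk("S", "L"))), c(0, 100))
  # silent Tyr: stays non-hydrophobic
  expect_equal(unname(hydrophobicity_shift(mk("Y", "Y"))), c(0, 0))
  # Pro -> Leu plus Ser -> Ser: half hydrophobic on both sides
  two <- rbind(mk("P", "L"), mk("S", "S"))
  expect_equal(unname(hydrophobicity_shift(two)), c(50, 50))
  # stops drop out of the denominator
  three <- rbind(mk("S", "L"), mk("Q", "*"))
  expect_equal(unname(hydrophobicity_shift(three)), c(0, 100))
  expect_error(hydrophobicity_shift(mk("S", "L")[0, ]), "no C-to-U")
})

test_that("type and frequency summaries are complete and conserved", {
  s <- rbind(site_row(1, "F", "C", "U", depth = 10, alt_count = 10),
             site_row(2, "F", "C", "U", depth = 10, alt_count = 5),
             site_row(3, "R", "G", "A", depth = 10, alt_count = 1))
  tf <- type_frequency_summary(s)
  expect_equal(nrow(tf$types), 12L)
  expect_equal(tf$types$F[tf$types$type == "C>U"], 2L)
  expect_equal(tf$types$R[tf$types$type == "G>A"], 1L)
  expect_equal(sum(tf$types$F) + sum(tf$types$R), nrow(s))
  # frequency 1.0 lands in the 91-100% bin; exactly 0.1 in 1-10%
  expect_equal(tf$freq_bins$F[tf$freq_bins$bin == "91-100%"], 1L)
  expect_equal(tf$freq_bins$R[tf$freq_bins$bin == "1-10%"], 1L)

  rs <- random_site_table(60, seed = 4)
  tfr <- type_frequency_summary(rs)
  expect_equal(sum(tfr$types$F) + sum(tfr$types$R), 60L)
  expect_equal(sum(tfr$freq_bins$F) + sum(tfr$freq_bins$R), 60L)
})

test_that("upstream windows honor orientation and genome bounds", {
  set.seed(61)
  gseq <- paste(sample(c("A", "C", "G", "T"), 200, replace = TRUE),
                collapse = "")
  genome <- c(m = gseq)
  s <- rbind(site_row(100, "F", "C", "U"), site_row(100, "R", "G", "A"))
  w <- extract_upstream_windows(s, genome, span = 25)
  expect_equal(nchar(w[[1]]), 26L)
  expect_identical(unname(w[1]), substr(gseq, 75, 100))
  expect_identical(unname(w[2]), dna_revcomp(substr(gseq, 100, 125)))
  expect_warning(
    wd <- extract_upstream_windows(site_row(10, "F", "C", "U"), genome,
                                   span = 25),
    "dropped")
  expect_length(wd, 0L)
})
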