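---
title: "Strand-specific discovery of mitochondrial RNA editing with mitosre"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Strand-specific discovery of mitochondrial RNA editing with mitosre}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mitosre)
```

## The problem

Plant mitochondrial transcripts are heavily edited, predominantly by
cytidine deamination ("C to U"). With strand-specific RNA-Seq the two
strands of the mitogenome can be interrogated separately, which exposes a
striking phenomenon: at some genomic positions the transcripts of *both*
strands are edited — C-to-U on the sense transcript together with the
complementary G-to-A change on the antisense transcript. We call a
position with such a mirrored pair of calls a symmetrical RNA editing
(SRE) event.

`mitosre` implements the full discovery chain at desk scale: a synthetic
mitogenome and read generator with a written ground truth, an ungapped
mapper with an explicit mismatch budget, strand-partitioned pileup and
editing-site calling, DNA-variant exclusion, SRE pairing, functional
annotation of CDS edits, calibration of the mismatch budget, and
cross-species comparison on consensus coordinates of homologous CDS.
Because every stage runs against planted events, each claim the pipeline
makes is checkable against a known truth.

## Strand conventions

Reads are single-end under an FR strand-specific protocol, so a read's
orientation identifies the transcribed strand. Alignments whose reverse
complement matches the forward reference carry the SAM flag-16
convention and form strand group **R**; the rest form group **F**.
Pileups count bases in genome-forward space; calls are then re-expressed
in the transcript's own orientation (RNA space): group F keeps the
genome base, group R complements it, and T is written as U. A genomic
C-to-T mismatch therefore reads as C-to-U in group F and as G-to-A in
group R — exactly the mirrored pair that defines an SRE.

## The caller

Per (position, strand group) with coverage $d$, each non-reference base
with count $a$ is a candidate substitution. A candidate is called when

* $d \ge c_{\min}$ (default 5),
* $a/d \ge f_{\min}$ (default 0.1), and
* $P(X \ge a \mid X \sim \mathrm{Bin}(d, e/3)) \le p_{\max}$
  (default 0.05),

where $e$ is the assumed per-base sequencing error rate (default 0.01;
each specific miscall occurs at $e/3$ under a uniform miscall model).
The exact one-sided binomial tail was chosen because it is
self-contained and verifiable against direct summation; the upstream
tool the thresholds mirror does not document its test. If two or more
substitutions pass at one (position, strand group) the column is
discarded entirely — a position is only reported with a single editing
type — but each strand group is judged independently, since the strands
are called separately. No multiple-testing correction is applied by
default; Benjamini–Hochberg can be layered on the emitted p-values by
the user. The frequency denominator is the full column depth (all
bases), not ref+alt only; this is a documented choice, not an inferred
convention.

Apparent editing at genomic variant positions is DNA, not editing: a
high-quality DNA variant set (internal caller at coverage $\ge$ 10 and
frequency $\ge$ 0.1, substitutions only; indels via a minimal VCF
reader) removes any editing call at a substitution position or inside an
indel's reference span.

## The synthetic study

The generator emulates the features of a small plant mitogenome that
matter to the method:

* **Genome and genes** — 20–60 kb of random sequence carrying
  non-overlapping single-exon CDS genes on both strands (ATG start, no
  internal stop, stop codon, length a multiple of 3). Genes keep one
  read length away from the circular origin and two read lengths from
  each other, so reads never wrap and the sequence can be treated as
  linear.
* **Editing events** — C-to-U in transcript space, preferentially at
  codon position 1/2 cytidines of sense CDS (probability 0.8), where
  plant mitochondrial edits concentrate. A configurable fraction of
  edited positions carries exact mirrored pairs (SRE). Editing
  frequencies follow a mixture with 60% mass on 0.91–1.00 and the rest
  on 0.3–0.9, reflecting the observed dominance of near-complete
  editing; the true per-tissue frequency distribution is unknown, so
  this is a modelling choice.
* **Reads** — each gene produces sense reads to the target depth and
  antisense reads at half that depth. Pervasive antisense transcription
  is what makes SRE observable at all, and organellar genomes are
  transcribed far beyond annotated genes; the 0.5 ratio is a fixed
  design default. Read starts are drawn across the full transcript span
  (mitochondrial transcripts are polycistronic and extend beyond CDS
  bounds), so coverage is uniform across gene bodies and ramps down in
  the flanking margins. A 9:1 transcript-to-background ratio adds
  genome-wide background on both strands. Editing alleles appear in a
  read with probability equal to the site's editing frequency; DNA SNP
  alleles appear in reads of both strand groups at their allele
  frequency; sequencing errors are uniform substitutions.
* **Clusters** — an optional cluster specification forces several edits
  into one read length, the situation that defeats small mismatch
  budgets.

Default study conditions (the `default_config()`): 30 kb, 8 genes, 200
edited positions at 40% SRE, 50× sense depth, 100 bp reads, 0.5%
sequencing error, mapping budget k = 7, caller defaults as above. One
end-to-end run takes under a minute on one core; the test suite uses
smaller fixtures (6–10 kb, 10–60× depth) chosen to exercise the same
behaviour quickly.

## Mapping and the mismatch budget

The mapper scans every offset in both orientations and keeps the unique
placement with minimal Hamming distance if it is within the budget k;
ties are dropped rather than assigned, because a random assignment would
fabricate editing signal. `N` matches nothing. A brute-force scan is
deliberate: at ≤ 60 kb correctness and interpretability beat speed, and
the inner loop (C++, early exit) maps thousands of reads per second.
There is no quality-aware weighting — the budget stays interpretable as
a mismatch count, which is the quantity being calibrated.

Calibration re-runs the whole mapping-based chain over k = 2..10 and
scores each run against a consensus ("assembly-style") site set computed
once from the most permissive mapping: per strand column with coverage
≥ 5, the strict-majority base (> 50%), a site where it differs from the
reference. This stand-in captures what a strand-specific assembler
followed by genome comparison yields — the dominant RNA state, blind to
minor-frequency edits. Sensitivity is the shared fraction of the
consensus set, specificity the shared fraction of the mapping set, and
the selected k maximizes their harmonic mean (ties to the smaller k);
the full grid table is always emitted because "best combination" is a
judgement the user may want to make differently. The chain is re-mapped
per k; whether the original analysis shared one mapping across the grid
is not documented anywhere we could follow.

## Annotation

Sites are located by coordinate containment with precedence CDS >
intron > tRNA/rRNA > intergenic; genic sites are sense/antisense by
comparing strand group with the coding strand, intergenic sites are
labelled forward/reverse. Overlapping genes at a queried position are an
error — no precedence between genes is defined. CDS sites are named
`<gene>-<offset>` with the 1-based offset in the spliced transcript, the
conventional naming for plant mitochondrial editing sites. Codon
consequences use the standard genetic code (correct for land-plant
mitochondrial CDS; the table is configurable in principle but fixed
here): silent, start-gain (codon 1 becomes AUG — the ACG→AUG
initiation-codon creation), stop-gain, stop-loss, missense. The
hydrophobicity shift of edited codons uses the fixed residue set
{A, V, L, I, P, F, M, W, G, C}; "hydrophobic" has no universal
definition, so the set is a named constant that can be probed under
alternatives. Motif-ready upstream windows cover −25..0 in transcript
orientation (26 bases including the edited base; a 25-base exclusive
reading is obtainable by trimming), reverse-complemented for
reverse-group sites, dropped with a warning at genome ends.

## Cross-species conservation

Homologous CDS are grouped by shared gene name (an input manifest, not
sequence search). Each group is aligned by center-star: every member is
globally aligned (match +1, mismatch −1, linear gap −2 — fixed defaults;
no aligner parameters are documented for the original analysis) to the
member with the highest summed pairwise score, and the pairwise
alignments are merged on the center's coordinates. Sites conserve when
they fall in the same group, the same consensus column, the same
RNA-space substitution and the same orientation class; orientation is
normalized to transcript orientation first, so it is comparable even
when the homologs sit on different strands of their respective
mitogenomes. SRE conservation additionally requires the mirror-type
identity and reports pairwise and all-species counts. The paralog
cross-check (e.g. nuclear copies of mitochondrial DNA) translates site
coordinates through a global pairwise alignment and flags identical
calls, skipping columns where the two sequences disagree.

## Numerical choices and degenerate inputs

* Binomial tails come from `pbinom`; they agree with direct pmf
  summation to 10⁻¹² over depths up to 500.
* Frequency thresholds are compared with a 10⁻¹² guard so that a
  frequency of exactly 0.1 is accepted on any depth.
* Exact 50/50 consensus columns yield no consensus and no site.
* Empty method-1 or method-2 site sets make specificity or sensitivity
  undefined; grid rows are kept with `NA` scores and an all-degenerate
  grid refuses to select a k.
* Reference-N columns are skipped with a warning; `N` in reads
  contributes no pileup evidence.
* The SRE pairing is keyed by genomic position (one pair per position),
  and duplicate calls at one (position, strand group) are an error —
  the multi-type filter upstream makes them impossible.

## Known limitations

* At intermediate coverage (depth 5–10), a single sequencing error
  passes all three caller thresholds: its frequency is ≥ 0.1 by
  arithmetic and its binomial tail (≈ 0.02–0.03) clears 0.05. Coverage
  ramps at transcript margins therefore contribute a floor of singleton
  false calls, which bounds the precision of the default study at about
  0.92 (the acceptance script reports the measured value as
  `site_precision`). Raising the minimum alt-read count or applying BH
  correction removes these, at the cost of departing from the published
  threshold set the package reproduces.
* The simulator draws uniform, quality-less errors, no PCR duplicates,
  no indel sequencing errors, and single-end reads only; passing tests
  demonstrate correctness of the method's logic under these conditions,
  not robustness to every artefact of real libraries.
* The internal DNA caller is substitution-only; indel variants must
  arrive via VCF.
* Gene models in the generator are single-exon; spliced (intron-bearing)
  CDS are fully supported by the annotation code and exercised with
  hand-built models, but not emitted by the generator.
* The consensus "assembly-method" stand-in shares the read set with the
  mapping method rather than assembling independently; it inherits the
  mapping's coverage, though not its mismatch ceiling.
* Gap placement in pairwise alignment is ambiguous when the bases
  flanking an indel repeat; a site immediately adjacent to an indel can
  therefore land on a different consensus column in one species and drop
  out of its conservation cluster. This is a property of alignment
  itself, not of the clustering rule.
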