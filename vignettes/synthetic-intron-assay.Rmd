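---
title: "Quantifying splicing efficiency in massively parallel synthetic intron assays"
author: "splicelib"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying splicing efficiency in massively parallel synthetic intron assays}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The assay and what this package computes

A massively parallel splicing reporter in budding yeast places thousands of
designed intron variants into one fixed reporter locus. Each oligo carries a
unique 12-nt barcode followed by a 158-nt variable region; in the
combinatorial subset a 6-nt donor site (5'SS) occupies oligo positions 18-23
(1-based from the barcode start), the intron runs from position 18 to
`18 + L - 1` for intron length `L`, the acceptor triplet (3'SS) is the last
three intron bases, the 7-nt branch site (BS) ends a configurable distance
before the intron end, and a short U-rich element sits immediately upstream
of the acceptor. Targeted amplicon sequencing of the region, for RNA and a
matched DNA control, yields merged reads starting at the barcode; the
computational task is to turn those reads into per-variant splicing
efficiencies (SE), cryptic-isoform calls, summary statistics and a
predictive sequence model. `splicelib` implements that machinery end to end,
plus a synthetic-read generator with known ground truth so every stage is
testable without sequencing data.

Splicing efficiency of an isoform is its read fraction:

$$\mathrm{SE} = \frac{\text{spliced isoform abundance}}{\text{total RNA abundance of the variant}}$$

and a variant's total RNA abundance relative to the pool is

$$\mathrm{abundance}(x) = \log_{10}\frac{\mathrm{RNAfreq}(x)}{\mathrm{DNAfreq}(x)}.$$

## Read classification by junction alignment

Reads are decoded to variants by the first 12 nt: a read is assigned when
exactly one library barcode lies within Levenshtein distance 2 (distance
"< 3", strict) of its prefix; windows of 11-13 nt are scanned so an indel
inside the barcode does not shift the comparison. Barcode sets are built
with pairwise edit distance >= 4, so every single substitution, insertion or
deletion decodes uniquely.

Classification uses 40-nt reference junctions (20 nt each side of a splice
boundary, truncated only at oligo ends) and the normalized local alignment
score

$$\mathrm{score} = \frac{SW(\text{junction}, \text{read})}{SW(\text{junction}, \text{junction})},$$

with a junction called positively aligned when the score exceeds 0.8.
Scoring defaults are the classic nucleotide local-alignment choices (match
+5, mismatch -4, gap 8) in the convention where a gap of length $L$ costs
$\mathrm{open} + (L-1)\,\mathrm{extend}$; all four values are configurable,
and the normalized score is invariant to rescaling them. Junctions truncated
at the oligo ends are shorter than 40 nt and are automatically renormalized
through their self-score. A read is *unspliced* when both exon-intron
junctions are positive and the exon-exon junction is not, *designed spliced*
in the mirror case, and *undetermined* otherwise.

Two-intron designs use eight reference junctions and five rule sets
(intron 1 only, intron 2 only, exon skipping, both introns, unspliced). The
rules are evaluated most-specific first: a both-introns-spliced read also
satisfies the single-intron conditions whenever the middle exon is at least
as wide as the junction flank, so the fully spliced isoform must be tested
before the single-intron ones, then exon skipping, then the single-intron
rules, then unspliced; reads matching no rule are unclassified.

## Cryptic isoform discovery

Undetermined reads are searched for cryptic spliced isoforms by aligning the
read against the full unspliced design and interpreting the single longest
uninterrupted reference gap as the excised intron. Two numerical choices
here deserve explanation.

**Fit alignment, not pure local alignment.** The read is aligned globally
(free end gaps on the design only). Under this geometry the score test is
coherent in the direction that first looks surprising: an unspliced read
scores ~1.0 of the design self-score, while a spliced read *pays* the
long-gap penalty and scores low, so a read is a cryptic candidate when its
normalized score falls **below** 0.7 (and carries fewer than 6 mismatches,
strict). Under a pure local alignment the same rule set cannot work at all,
for a structural reason: only 17 nt (12-nt barcode + 5-nt exon lead) precede
the intron, worth at most 85 score points, so any gap opening cost near or
above 85 is never bridged — the optimizer simply drops or misaligns the 5'
prefix and reports no gap. The comparison direction is still exposed as a
configuration flag.

**Gap costs.** For the same reason the cryptic-mode gap parameters must
keep the opening below the 17-nt anchor's worth: the defaults are opening
12 and extension 0.25, which bridge gaps up to roughly 290 nt while a
single-base gap still costs more than a mismatch, so isolated sequencing
errors stay substitutions and a spliced-out segment surfaces as one long
uninterrupted gap. A very high opening cost with cheap extension (the
intuitive "one long gap" setting) fails the anchor bound and is therefore
not usable as a default; it remains available through the configuration.

Equal-score gap placements are genuinely ambiguous when the bases flanking
the gap repeat; inferred gaps are canonicalized by sliding
sequence-equivalent placements toward the designed donor position, since the
5'SS is the biologically anchored end (the vast majority of cryptic events
reuse the designed donor with an alternative acceptor). Calls are clustered
by their exact (5' end, 3' end) pair; a cluster matching the designed ends
is reassigned to the designed isoform, and clusters are reported only when
their aggregated SE exceeds 0.01. A cryptic acceptor closer than ~20 nt to
the read end leaves too little exonic anchor for the gapped alignment and is
undetectable by construction; the generator therefore only plants cryptic
sites with at least 20 nt of downstream exon.

## Splicing-efficiency aggregation and filters

Within each (index, repeat) cell an isoform's SE is its read count over the
variant's total assigned reads in that cell — including undetermined reads
in the denominator by default (a configuration switch restricts the
denominator to classified reads). Repeats within an index are combined by a
read-count-weighted mean (equivalently, pooled counts), indices by the
median over indices with data (even counts average the central pair).
Because the median is taken per isoform, the aggregated efficiencies of a
variant are an exact partition only before the index median; after it they
can exceed 1 by a small sampling slack. Variants with fewer than 10 reads in
a sample are flagged and their efficiencies left undefined (never zero).
The identical pipeline runs on the DNA control; any intended or cryptic
isoform with DNA-sample SE above 0.05 (strict) is a synthesis or alignment
artifact and its RNA value is zeroed and flagged.

## The synthetic-data generator

The generator defines the study conditions the tests run under.

* **Copy numbers** are log-normal (meanlog 0, sdlog 1), emulating the wide
  abundance distribution of a pooled library.
* **Designed-spliced fractions** are, by default, a noisy logistic of the
  variant's regulatory features: the consensus branch site contributes the
  largest positive term, intronic GC is repressive, the U tract upstream of
  the 3'SS and a branch-site-to-acceptor distance of at most 30 nt are
  activating. A score-dependent dead mode (weak designs failing outright)
  makes the realized distribution bimodal, matching the observation that
  most designs are either mostly spliced or hardly spliced. The noise scale
  (s.d. 0.65 on the logit) is set so that predictability from sequence
  features is capped near the assay's replicate reproducibility
  (barcode-replicate correlations around 0.76) — the same ceiling argument
  the assay itself uses for its model performance. Draws are seeded from the
  variable-region sequence, so variants sharing a design (barcode
  replicates) share the same latent splicing state; this is what makes the
  barcode-quartet variance control meaningful. A sequence-independent
  bimodal mode is available for null experiments.
* **Cryptic isoforms** appear in a quarter of single-intron variants (when
  a usable downstream HAG motif exists) at low fractions (Beta(1, 25),
  median ~0.03), always reusing the designed donor.
* **Two-intron variants** draw a Dirichlet mixture over the five isoform
  classes, weighted toward unspliced and the single-intron isoforms.
* **RNA levels** couple to splicing: the RNA-sample copy number is the DNA
  copy number times $e^{1.2\,\mathrm{SE}_\mathrm{total}}$ times independent
  log-normal expression noise (s.d. 0.7). The coupling emulates the faster
  turnover of unspliced transcripts that underlies the assay's positive
  SE-abundance correlation; the noise keeps that correlation realistic
  rather than deterministic. The matched mock-variant control (independent
  log-normal unspliced and spliced levels) is uncorrelated *exactly*, by
  the unspliced/spliced exchange symmetry, so the pipeline's SE arithmetic
  cannot manufacture the correlation.
* **Errors** are i.i.d. substitutions (default rate 0.001); indels and
  quality-score realism are out of scope. Reads are emitted pre-merged and
  adapter-trimmed, starting at the barcode; control indexes (4) and repeats
  (2) are carried in read metadata, with an optional literal 8-nt index
  prefix layout.

What the generator does **not** emulate: PCR amplification bias, UMI-style
duplicates, real reporter background sequence (backgrounds are
ATG-scrubbed random sequence labelled synthetic), real genomes or real
ortholog sets (avoidance and delta-SE analyses run on simulated annotated
genomes and simulated species). Passing tests therefore demonstrate that
the computational pipeline is correct and well calibrated under these
conditions — not that any biological conclusion transfers to a particular
real dataset.

## Library design choices

* **Coordinates** are 1-based closed intervals counted from the barcode's
  first base, which makes "the donor occupies positions 18-23" literal.
* **BS-to-3'SS distance** is the number of nucleotides from the first base
  after the 7-nt branch-site motif through the final intron base, inclusive
  of the acceptor triplet.
* **Start-codon scrubbing** removes every ATG at any offset by a
  deterministic 5'-to-3' scan, mutating the G first and choosing the first
  substitution that creates no new ATG; splice-site motifs are protected,
  and a protected donor containing ATG (e.g. the consensus GTATGT) instead
  receives a TAA stop codon two codons downstream, in the ATG's frame.
* **Two-intron layout**: a fixed 5-nt exonic lead precedes the first intron
  (mirroring the 5-nt flank convention of natural-intron insertions) and a
  fixed 15-nt exon follows the second intron. The 15-nt tail is a
  deliberate departure from a literal 5-nt mirror: with only 5 nt of third
  exon the intron2-exon3 reference junction is 25 nt, and its 20-nt
  intronic half — a U-rich tail plus YAG, like every intron end —
  cross-matches the retained first intron's tail in intron2-only spliced
  reads above the 0.8 threshold, leaving those reads unclassifiable. At 15
  nt the junction is wide enough to discriminate. Two-intron pool introns
  are drawn at 52-62 nt so every ordered pair leaves a middle exon of at
  least 14 nt.
* **Degenerate branch-site templates** (NNCTAAC, NNCTAAT, NNTTAAC) are
  instantiated by seeded uniform draws over the two degenerate positions, a
  configurable number of instances per template.
* **Mock negative-control sites** are drawn once per catalog from the seed
  (ATG-free, distinct from all real sites, the mock acceptor not ending in
  AG) and recorded, so negative controls use the same geometry with
  non-functional sites.
* **Structure mutants** mutate positions near (never inside) a splice-site
  motif and accept the first mutant whose local window folds the entire
  site into base pairs under the fold engine.

## Statistics

**Motif avoidance.** Introns are registered at their 3' end (last intron
base = position 0, strand-resolved; negative offsets intronic), and
$f_\mathrm{motif}(i)$ counts introns whose 3-mer *starting* at offset $i$
matches an acceptor motif (CAG/TAG). The test compares the summed frequency
in the upstream window (offsets -32..-3, taken literally, i.e. excluding
the acceptor triplet itself at -2..0) and the downstream window (+1..+30)
against control sets of N random coding-strand positions (N = number of
introns), drawn without replacement when possible:

$$p = \frac{\#\{\text{control sets with window sum} < \text{introns' window sum}\}}{n_\mathrm{controls}}.$$

The display window for profiles is -50..+30. Under null placement
(intron anchors drawn from the control distribution) the p-value is
uniform up to the strict-inequality discreteness; the test suite verifies
calibration over 200 replicate genomes and detection of planted depletion.

**Cramer's V.** SE values are categorized as unspliced (SE <= `zero`,
default exactly 0), intermediate (up to 0.5) and high; the statistic is
$\phi_C = \sqrt{\chi^2 / (n\,(k-1))}$ with $k = 3$ and no continuity
correction. When one side of the comparison is a continuous model
prediction, the unspliced boundary must be lifted above 0 (fold-averaged
regression output never reaches 0 exactly); the analysis scripts use 0.2
for that comparison.

**Controls.** The barcode-quartet control compares the mean within-group SE
variance of designs measured under several barcodes against shuffled groups
of the same sizes (10^4 shuffles); the randomized-abundance control rebuilds
SE and abundance from independent log-normal mock levels and reports the
(null) correlation.

**Ortholog comparison.** `delta_se` pairs each foreign intron with the
reference-species intron of the same gene, reports
$\Delta SE = SE_\mathrm{ortholog} - SE_\mathrm{reference}$ and the
per-species percentage with $\Delta SE > 0$ (ties are not "better").

## The predictive model

Every single-intron variant maps to a frozen 39-feature schema: the three
splice-site sequences, the U element and the background as categorical
features, plus length/distance parameters, composition features (GC, A and
U/Y content in the 20-nt window upstream of the acceptor, with the C
fraction among pyrimidines and the longest U run), predicted local
secondary structure at each site and over the intron, consensus indicator
features, positional features, and HAG-motif context around the acceptor.
The schema is a documented object (`feature_schema()`); any change to the
composition is a schema update, not a code change. Natural-intron
insertions, which record no branch site, get one located as the best
consensus match containing the catalytic A (ties toward the 3' end, where
yeast branch sites sit); missing U elements are encoded as `"none"` with
length 0, and a missing downstream-HAG distance is imputed as the
downstream exon length + 1.

The default structure engine is a Nussinov maximum base-pairing dynamic
program (Watson-Crick plus G:U pairs, minimum hairpin loop 3), with score
= minus the pair count as a dependency-free free-energy proxy; an external
`RNAfold` backend or any user function can be plugged in for true minimum
free energies.

Training follows 5-fold averaging cross-validation: a 75/25 train/test
split (test size `round(0.25 N)`; 12,667 variants give a 3,167-item test
set), five leaf-wise boosted-tree models (50 leaves, learning rate 0.1,
feature fraction 0.8, bagging fraction 0.8, up to 500 rounds with early
stopping after 5 stagnant validation rounds), each trained on four folds
with the fifth as the early-stopping validation set; the test prediction is
the mean of the five models. The bagging-frequency parameter of the
reference leaf-wise implementation has no equivalent in the xgboost
backend, which re-subsamples every round; it is recorded in the
configuration for fidelity but is inert. Feature importance uses exact
tree-Shapley attributions on the training set, averaged over the five fold
models, with one-hot member columns summed back to their schema feature;
attributions plus the base value reproduce each prediction exactly (local
accuracy), and confidence intervals come from 1000 bootstrap resamples of
the observations.

## Problem sizes and reproducibility

The test suite and the acceptance script run simulations at sizes chosen to
make their statistical assertions sharp while staying desk-scale: SE
recovery uses 200 variants at 2,000 reads each (error rate 0.001), cryptic
recovery ~25 injected isoforms at zero error, classification soundness 10^4
reads, avoidance calibration 200 replicate genomes at 10^3 control sets
(10^4 for the planted-depletion check), and the model stages 300-650
variants. The alignment oracle is exhaustive over all sequence pairs up to
length 4 over a two-letter alphabet plus hundreds of random longer pairs.
Every stochastic stage takes an explicit seed; one global seed fans out to
per-stage sub-seeds through a documented derivation (`derive_seed`), so
stages are independently reproducible and identical seeds give
byte-identical outputs.

## Known limitations

* Alternative *donor* usage producing lariat intermediates is invisible to
  the assay and out of scope, as are isoforms requiring more than one gap.
* Cryptic acceptors within ~20 nt of the read end cannot be called (no
  alignment anchor), and cryptic introns shorter than ~37 nt score above
  the 0.7 fit-score threshold and are not called — both inherent to the
  printed call rules, not implementation limits.
* The index-median aggregation does not exactly preserve the additivity of
  isoform fractions (see above).
* The simulated genomes used by the avoidance analyses are homogeneous
  random sequence; real genomes have composition structure that would widen
  the control distribution but not change the test's logic.
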