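---
title: "Methods: dual-organism metatranscriptome analysis of ectomycorrhizal symbiosis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: dual-organism metatranscriptome analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The scientific problem

Ectomycorrhizal fungi such as *Suillus* form mutualistic root symbioses with
pine hosts, but only with *compatible* host species: an incompatible pairing
fails to build the fungal mantle and Hartig net. RNA-seq of inoculated root
tips therefore yields a *mixed* transcriptome — plant, fungus, ribosomal RNA
carry-over, and bacterial contamination — whose fungal portion varies
enormously with the outcome of the interaction (roughly half of all reads in
compatible pairings versus a few percent in incompatible ones). The analysis
task is to (i) attribute every read to its source organism, (ii) recover
fungal genes missing from the pure-culture references by de novo assembly,
(iii) detect genes a fungus upregulates in response to a particular host,
(iv) compare those responses *across* fungal species to separate a shared
("common") symbiosis program from pair-specific ("unique") genes, and (v)
screen the responsive gene set for candidate effectors — small secreted
proteins (SSPs).

`symbiotrx` implements this pipeline end to end, together with a synthetic
data generator that plants every structure the pipeline is supposed to
recover, so each stage is testable offline against a known truth.

# Pipeline stages and their models

## Tiered read partitioning

Reads are mapped sequentially against four reference panels — fungal rRNA,
bacterial 16S, the inoculated symbiont's pure-culture transcript contigs,
and the host EST set — and the first tier whose mapping passes the threshold
claims the read ("first match wins"). Mapping is seed-and-extend: a 21-mer
seed (odd `k`, both strands) anchors a full-length ungapped comparison,
accepted when the mismatch fraction is at most `max_mm_frac` (default 0.05).
Ungapped extension is adequate here because the simulated error model is
substitution-only and desk-scale references are unspliced transcripts; ties
are broken deterministically by reference name, offset, then strand.
Samples from uninoculated control roots have no inoculated species, so the
symbiont tier uses the union of all culture panels for them.

## De novo assembly of the unassigned pool

Reads claimed by no tier are pooled across samples and assembled with a de
Bruijn unitig assembler: canonical `k`-mers (default `k = 31`) are counted,
those below `min_support` (default 2) are dropped, and maximal
non-branching paths are emitted as contigs, canonically oriented and
deterministically ordered. Two deliberate simplifications:

* **No bubble popping.** At high coverage, two reads that independently make
  the same sequencing error create a surviving "bubble" branch that
  fragments unitigs. Rather than implement bubble removal, the pipeline
  applies a coverage cutoff (`auto_cutoff_frac`, default 0.05): k-mers whose
  count falls below 5% of the occurrence-weighted median k-mer coverage are
  pruned. At low coverage this reduces to plain `min_support`.
* **End trimming.** Terminal k-mers covered by a single read are pruned when
  `min_support > 1`, so assembled contigs may lose a base or two at each
  end. Lossless reconstruction is exact at `min_support = 1`.

Contigs shorter than `min_contig_len` (default 200 nt, a Trinity-like
floor) are discarded before classification.

## Contig classification

Each retained contig is translated in six frames and locally aligned
(Smith–Waterman, linear gap, BLOSUM62) against fungal and plant protein
panels; the higher-scoring panel wins if the alignment reaches
`min_identity` (0.35) over `min_coverage` (0.5) of the shorter protein,
otherwise the contig is `other`. A score-only batched alignment pass
shortlists the best panel candidate before the full traceback alignment is
recomputed for it. Fungal-classified contigs join the symbiont gene
universe for quantification; plant ones the host universe; `other` is
reported but not quantified.

## Quantification and normalization

Reads in the fungal bins are re-mapped against the species' gene universe;
a read is counted for its uniquely best contig, and reads tied across
contigs are dropped and tallied as ambiguous. Size factors are
median-of-ratios: the per-contig reference is the geometric mean across
samples (contigs with any zero excluded), and a sample's factor is the
median ratio to that reference. This is the same estimator the DESeq family
uses; the package authors it directly and cross-checks it against DESeq2 in
the test suite.

## Differential expression gating

For each (symbiont, host) pair the contrast compares the pair's replicates
(n = 3 compatible, n = 2 incompatible) against the same species' free-living
mycelium reference samples. Gating combines, conjunctively by default:

* Welch's unequal-variance t-test at `p < 0.01`,
* at least 2-fold change (`|log2FC| >= 1`, computed on normalized group
  means with pseudocount 1), and
* Benjamini–Hochberg FDR < 5% (step-up, authored and cross-checked against
  both the brute-force definition and `p.adjust`).

Either significance gate can be disabled to reproduce analyses that used
only one of them.

**Why the t-test runs on the log scale.** With two replicates per group and
count-scale (Poisson-like) noise, the group with the larger expression
dominates the variance, and the Welch–Satterthwaite degrees of freedom
degenerate towards 1; the two-sided critical value at df = 1 and p = 0.01
is 63.7, unreachable at any sequencing depth. Testing
`log2(normalized + pseudocount)` values stabilizes the variance so both
groups contribute comparably to the df. This is standard practice in
log-linear DE frameworks; `test_scale = "observed"` restores the raw-scale
test. Even so, contrasts with n = 2 on both sides remain the least powered
part of the design: the variance estimate itself is noisy (an F(1,1)-tailed
ratio), and a minority of genuinely responsive genes will fail `p < 0.01`
in incompatible pairings. The free-living mycelium baseline uses 4
replicates by default precisely to keep one side of that variance stable.

## Common and unique gene sets

Per-pair upregulated sets are compared across species at the protein level:
each gene's longest *complete* ORF (complete start-to-stop ORFs are
preferred over open-ended readthrough frames, which can spuriously outgrow
the coding frame by a few residues) is aligned across species, an edge is
drawn at identity ≥ 0.35 over ≥ 0.5 coverage of the shorter protein, and
clusters are connected components (single-linkage, deterministic). Then:

* **common-compatible** clusters have at least one member in the
  compatible-upregulated set of *every* symbiont species that has a
  compatible pairing (likewise common-incompatible; species without a
  pairing of that label are excluded from the quantifier);
* a gene is **unique** to its pair when it is upregulated there and its
  cluster contains no other species' upregulated member. This is the
  expression-set definition of uniqueness: absence from another species'
  *genome* cannot be established from expression data and is deliberately
  not claimed.

## SSP effector classification

Candidate effectors satisfy four criteria conjunctively: (a) length < 300
residues; (b) an N-terminal signal peptide; (c) no transmembrane segment;
(d) no C-terminal `[KH]DEL` ER-retention motif. Signal peptides use a
transparent von Heijne-style heuristic — at least one K/R in residues 1–5,
a ≥ 7-residue h-region within positions 2–25 with mean Kyte–Doolittle
hydropathy ≥ 2.0, and a (−3,−1) small-residue cleavage site in positions
15–35. Transmembrane segments are 19-residue windows with mean hydropathy
≥ 1.6, excluding windows overlapping the predicted signal peptide.
N-glycosylation sequons (`N-X-[ST]`, X ≠ P), RXLR (within 60 residues after
cleavage, the oomycete-effector convention) and a monopartite importin-α
NLS consensus (`K(K/R)X(K/R)`) are annotated but do not gate the call; the
NLS is reported because nuclear import would argue against an extracellular
role. Outputs of dedicated external predictors can be plugged in through
`classify_ssp(..., overrides = )`.

# The synthetic data generator

The generator is first-class, tested code, not a fixture. Its defaults
encode the study conditions the pipeline is meant to handle:

| Parameter | Default | Meaning |
|---|---|---|
| design | 4 × 3 grid | 4 *Suillus* × 3 *Pinus*; 9 compatible, 3 incompatible |
| replicates | 3 / 2 | per compatible / incompatible pairing |
| mycelium, controls | 4 / 2 | free-living fungal and uninoculated-root samples |
| fungal read fraction | 0.51 / 0.061 | compatible / incompatible samples |
| rRNA, 16S fractions | 0.05 / 0.02 | decoy carry-over |
| reads per sample | 50,000 | desk-scale depth |
| read length, error | 100 nt, 0.005 | substitution-only errors |
| common families | 10 + 4 | compatible- and incompatible-responsive ortholog families |
| ortholog divergence | 0.05 | nucleotide divergence between family members |
| unique genes | 3 per pair | one of them SSP-positive |
| background genes | 30 per species | 6 withheld from the culture reference ("novel") |
| fold change | 8 | planted responsive over-expression |

Bin sizes are exact (stratified sampling), so composition assertions in
tests are exact; reads are drawn uniformly over transcript positions with
50% reverse-complement. Ortholog families are built from an ancestral
protein, reverse-translated once, then mutated per species at the
nucleotide level with substitutions that would create in-frame stops
rejected, which keeps every family member's ORF intact while bounding
nucleotide identity. Planted SSP positives follow the signal-peptide
template exactly; each planted negative violates exactly one named
criterion, which makes the classifier's truth table fully determined.

Depth and replication were chosen by a priori power analysis of the Welch
gates (see above): 50,000 reads/sample and a 4-replicate mycelium baseline
put compatible contrasts far above threshold and the n = 2 incompatible
contrasts near but above it for 8-fold planted effects.

**What passing tests do and do not show.** The generator emulates the
*statistical* structure — composition shifts, replicate design, planted
homology, planted effects — with uniform position coverage, substitution
errors only, no isoforms, no PCR duplication, no overdispersion beyond
multinomial sampling, and no realistic quality profiles. Recovery results
on it validate the pipeline's logic and thresholds, not performance on real
library chemistry; in particular real RNA-seq overdispersion would lower DE
power relative to these conditions.

# Numerical and design choices

* Determinism everywhere: per-sample random streams are derived from the
  single config seed and sample identity, so regeneration is byte-identical
  and order-independent; mapping ties, contig orientation/order and
  component enumeration all have fixed tie-breaks.
* `welch_t`, `bh_adjust` and `size_factors` are authored implementations
  (they are the method's statistical core); `stats::t.test`, `p.adjust` and
  `DESeq2::estimateSizeFactorsForMatrix` serve as independent cross-checks
  in the test suite only.
* Degenerate inputs: zero-variance groups give t = 0/±Inf with p = 1/0;
  all-zero contigs are reported `untested`; a count matrix with no
  zero-free contig fails normalization with advice rather than silently
  producing factors.
* The per-pair fold-change baseline is explicit (mycelium reference) rather
  than inferred, because several published summaries anchor fold changes to
  different baselines; any contrast can be recomputed with
  `differential()` directly.
* Venn summaries operate on cluster ids (so species contribute comparable
  units) and support 2–6 sets.

# Problem sizes

Module tests run on a reduced configuration (1,500 reads/sample, 3 + 2
families, 10 background genes per species); recovery checks and the
acceptance script run the full default conditions above (55 samples,
2.75 M reads, ~250 genes), which completes in under ten minutes on one
CPU. The acceptance script (`scripts/acceptance.R`) regenerates everything
from scratch under the supplied seed and reports the measured quantities as
JSON.

# Known limitations

* Single-symbiont samples are assumed: reads are attributed to the
  inoculated species, not disambiguated among symbionts.
* Paired-end reads, spliced alignment, isoforms, scaffolding and bubble
  popping are out of scope.
* The homology threshold (0.35 identity / 0.5 coverage) is a remote-homology
  convention, exposed as a parameter, not a fitted value.
* The signal-peptide and TM heuristics are transparent approximations of
  dedicated predictors; the `overrides` hook exists to substitute real
  predictor output.
* Incompatible contrasts at n = 2 are intrinsically underpowered under
  strict p gating; reported sensitivities for incompatible-condition gene
  sets should be read with that in mind.
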