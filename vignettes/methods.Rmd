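---
title: "Cross-species coexpression and phylogenetics: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Cross-species coexpression and phylogenetics: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Genes of a plant specialized-metabolism pathway are rarely clustered in the
genome, but they are co-regulated: enzymes needed together are transcribed
together. Given a handful of *bait* genes already known to act in a pathway,
guilt-by-association says that genes whose expression tracks the baits are
candidates for the same pathway. A single-species coexpression scan is noisy;
requiring that the same association appears independently in several species,
in genes that are also each other's sequence homologs, filters out most
spurious hits. OCGfinder implements this combination end to end and summarizes
the evidence per *Orthologous Coexpressed Group* (OCG): a cluster of
cross-species homologs containing coexpressed members from multiple species,
with a functional annotation, a reliability score and a gene tree.

## Pipeline model

1. **Coexpression scan (per species).** Every gene is correlated with every
   bait by Spearman's rank correlation $r_s$ computed on average ranks, with
   the two-sided p-value from the t approximation
   $t = r_s\sqrt{(n-2)/(1-r_s^2)}$. A gene is a candidate iff
   $r_s \ge$ `rCutoff` for at least one bait, the corresponding p-value is
   $\le$ `pCutoff`, and its cumulative TPM over all samples is
   $\ge$ `minExpCutoff`. Candidates are ranked by their best coefficient and
   truncated to `numCut` per species; the baits join the candidate set with
   $r_s = 1$. Spearman is used deliberately: it captures monotone but
   non-linear dose-response relationships, which are common between a
   regulator's activity and downstream transcript abundance.
2. **Ortholog collection.** Candidate peptides (CDS translated in frame +1)
   are searched against every species' proteome. A hit survives iff
   e-value $\le$ `evalueCutoff`, bit score $>$ `scoreCutoff`, alignment
   length $>$ `lenCutoff` and percent identity $>$ `simCutoff`; subjects of
   surviving hits join the collection.
3. **OCG extraction.** The combined collection is searched all-vs-all; the
   filtered hits define an undirected graph whose connected components are
   the OCG candidates. A component is retained iff it has at least
   `minOcgSize` sequences and its coexpressed members span at least
   `minCoexpSpecies` species. Retained OCGs are ranked by coexpression ratio
   (coexpressed members / total members) and labelled `0000`, `0001`, ...
4. **Annotation (optional).** A random subsample of each OCG
   (`seqsClusterAnno` percent, floored at 10% and at five sequences) is
   searched against a reference peptide set; each sequence votes for its
   best-bit-score reference, the modal vote wins, and the reliability score
   is the winning fraction of the sample.
5. **Alignment, trimming, tree.** Each OCG is globally aligned, columns with
   non-gap occupancy below `occupancy` percent are removed, and a tree is
   inferred from the trimmed alignment, written in Newick form together with
   iTOL annotation sidecars that mark coexpressed leaves and colour them by
   their best coefficient.

## Parameters

| Parameter | Default | Unit | Role |
|---|---|---|---|
| `rCutoff` | 0.7 | Spearman coefficient | minimum bait correlation |
| `pCutoff` | 0.05 | probability | maximum correlation p-value |
| `numCut` | 100 | genes | per-species candidate cap |
| `minExpCutoff` | 30 | cumulative TPM | excludes near-silent technical artifacts |
| `evalueCutoff` | 1e-5 | e-value | similarity filter (inclusive) |
| `scoreCutoff` | 100 | bits | similarity filter (strict) |
| `lenCutoff` | 100 | alignment columns | similarity filter (strict) |
| `simCutoff` | 80 | % identity | similarity filter (strict) |
| `occupancy` | 10 | % non-gap | alignment column retention (inclusive) |
| `seqsClusterAnno` | 50 | % of OCG | annotation subsample (min 10%, ≥5 seqs) |
| `minOcgSize` | 10 | sequences | OCG retention |
| `minCoexpSpecies` | 3 | species | OCG retention |
| `seed` | 1 | integer | all random draws |

Threshold strictness follows the way each rule is conventionally phrased:
the e-value cutoff is "must not exceed" (inclusive), while score, length and
identity are "greater than" (strict); the correlation, p-value, expression
and occupancy cutoffs are inclusive. These conventions are frozen in the
test suite as exact boundary cases, so changing any of them is a visible,
deliberate act.

## Deliberate readings of ambiguous points

* **p-value adjustment.** The p-value used by the scan is the plain
  two-sided test p-value per (gene, bait) pair. A Benjamini–Hochberg switch
  (`adjustP`) exists but is off by default; with hundreds of genes per
  species the raw p-value at the default `rCutoff` is rarely the binding
  constraint anyway.
* **Candidate cap.** `numCut` caps candidates per species (per scan), not
  per bait: the scan is one analysis per species with the gene's best bait.
* **Coexpression ratio.** Baits count as coexpressed members in both the
  numerator and denominator; they carry the same `_coexp` tag downstream.
* **Edges.** One surviving hit in either direction creates an edge;
  reciprocity is not required. Self-hits are removed before graph
  construction.
* **Ties.** Every tie (isoform length, candidate rank, bit score, modal
  annotation vote, OCG rank) is broken lexicographically, making all outputs
  deterministic for a fixed seed.
* **iTOL sidecars.** Coexpressed leaves are marked with a `DATASET_BINARY`
  dataset (the simplest dataset type carrying a per-leaf flag); the
  coefficient gradient uses `DATASET_GRADIENT` anchored at
  [`rCutoff`, 1.0], so a bait always maps to the maximum colour.
* **Isoform reduction** requires an explicit transcript-to-gene mapping
  rather than guessing a header suffix convention; a wrong silent guess is
  worse than asking for the mapping.

## Built-in engines and numerical choices

The external tools a practitioner would use (DIAMOND/BLAST+, MAFFT/MUSCLE,
FastTree/RAxML-NG/IQ-TREE) are available through adapters that pass exactly
the documented options (`-wag -nosupport` for FastTree, `LG+G8+F` for
RAxML-NG). Alongside them the package ships exact built-in engines, so every
stage runs and is testable with no binaries installed:

* **Search:** Smith–Waterman local alignment with BLOSUM62, gap open 11 /
  extension 1. Raw scores are converted to bits with the standard gapped
  Karlin–Altschul constants ($\lambda = 0.267$, $K = 0.041$) and e-values as
  $m n 2^{-\mathrm{bits}}$. The constants are approximate by nature; bit
  scores and e-values are comparable within a run of this engine, and tests
  never compare them against an external aligner's values.
* **Alignment:** center-star progressive alignment. The center sequence
  maximizes the summed pairwise global-alignment score; all others are
  aligned to it pairwise and merged on the center's coordinates ("once a
  gap, always a gap"). Degapping any output row reproduces its input
  sequence exactly — an invariant the tests enforce.
* **Tree:** p-distances (mismatches over shared non-gap columns) and
  neighbor joining. A pair sharing no columns gets 1.1 times the maximum
  observed distance (with a warning); small negative branch lengths from the
  NJ algebra are clamped to zero; trees are left unrooted — display rooting
  is the viewer's job.

Genes with constant expression have undefined rank correlation; they are
skipped and counted, not errors. CDS with internal stop codons translate the
stop as `X` with a warning; a trailing stop codon and a trailing 1–2 nt
remainder are dropped.

## The synthetic-data generator

`syntheticSpec()` describes the reference study condition used by the test
suite and the acceptance script: 5 species, 12 orthologous families present
in every species with 2 paralogous copies, families 1–4 forming the pathway
module, 50 samples per species, ancestral CDS of 600–1200 nt, within-family
peptide identity targeted at 90%, log-normal expression noise with sd 0.25.
Those sizes keep each family above the OCG size threshold (5 species × 2
copies = 10 members) while one copy per species carries the coexpression
signal, so the retention rules are exercised on both margins.

Expression is built from one latent pathway-activity trajectory per species
spanning two orders of magnitude of TPM; module genes are monotone power
transforms of it times log-normal noise. Monotone transforms preserve ranks,
so the achieved Spearman correlation is controlled directly by the noise
level rather than indirectly through an additive model. Families are
substitution-only mutants of a random ancestral CDS (codon replacement rate
$(1 - \mathrm{identity}/100) \times 0.4$ per lineage, chosen so realized
pairwise identity sits at or slightly above the target and clear of the 80%
similarity filter); stop codons are never introduced. Ancestral CDS lengths
are drawn from 600–1200 nt so that every within-family alignment exceeds the
100-column length filter.

What the generator does **not** emulate: codon usage and GC bias, indels
(available as an option but off by default so alignment-length filters
behave predictably), read-level sampling noise, shared regulatory programs
between module and background genes, unequal species sampling, and missing
orthologs. Passing tests on this generator therefore demonstrate the
correctness of the machinery and its thresholds, not the biological error
rate on real transcriptome compendia.

## Problem sizes and verification

The test suite runs each operation's documented boundary cases and the
property suites: Spearman vs a rank-then-Pearson oracle (1,000 random
vectors, 1e-12), connected components vs a transitive-closure oracle
(exhaustive over all 4-node graphs, 1,000 random graphs to 8 nodes),
occupancy-trim idempotence and conservation, NJ topology recovery on 200
additive matrices from random trees (4–8 taxa), subsample-size monotonicity,
MD5 reference digests, Newick round-trips, and the end-to-end planted-module
recovery on the reference condition, which must reach precision and recall
1.0 with the correct reference annotation for every OCG. A three-level noise
ladder checks that recall degrades monotonically as expression noise grows.
These sizes were chosen so the whole suite completes in well under a minute
per module on a single CPU while still exercising every code path.

## Limitations

* Connected components merge families bridged by a single promiscuous hit;
  no community detection is attempted, by design.
* The reliability score conflates "no annotation found" with "disagreeing
  annotations" only insofar as unannotated sequences vote for an explicit
  sentinel; the functional table makes the distinction visible.
* Built-in e-values use fixed Karlin–Altschul constants and are therefore
  approximate; for publication-grade similarity statistics use the DIAMOND
  or BLAST+ adapter.
* Annotation against a single reference species cannot name functions that
  species lacks; multi-species references are the obvious extension.
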