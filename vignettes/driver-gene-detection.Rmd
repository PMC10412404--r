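---
title: "Impact-weighted driver-gene detection in laboratory evolution"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Impact-weighted driver-gene detection in laboratory evolution}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(eadriver)
options(eadriver.verbose = FALSE)
```

## The model

Adaptive laboratory evolution (ALE) produces replicate lineages of a
bacterium adapted to a selective pressure; sequencing the evolved clones
yields a pooled set of single-nucleotide variants. The inference problem is
to separate *driver* genes — those whose mutations cause the adapted
phenotype — from genes that simply accumulated neutral passengers. Pure
mutation-frequency ranking answers "which genes are mutated more often than
their length predicts", which is necessary but not sufficient: a long,
mutation-tolerant gene can out-count a short gene carrying two
function-breaking substitutions.

`eadriver` adds the functional dimension through Evolutionary Action (EA)
scores: a precomputed table assigning each possible missense substitution
in each protein a score in [0, 100], higher meaning more disruptive to the
protein's evolved function. The package consumes EA tables as input; it
does not compute them from alignments.

Three per-gene statistics are computed against a *mutation background* —
the null distribution of EA scores a gene would show if mutations hit it
indifferently:

1. **EA_KS.** The one-sided two-sample Kolmogorov–Smirnov statistic
   $D^+ = \sup_x [F_{bg}(x) - F_{obs}(x)]$ between the gene's observed EA
   scores ($n$ values) and its background pool ($m$ values). Only an
   upward shift of the observed distribution registers; a gene whose
   mutations are *milder* than background gets $D^+ = 0$. The p-value is
   the asymptotic one-sided form $\exp(-2 (D^+)^2 nm/(n+m))$, floored at
   machine precision and capped at 1. For the $n = 1$–$3$ counts typical
   of a single gene this approximation is conservative (the suite verifies
   this empirically), which we prefer to an anti-conservative exact-ish
   alternative.

2. **EA_sum.** The burden $S = \sum_i x_i$ over the gene's scored missense
   mutations, against a Monte-Carlo null: `n_mc` resamples of $n$ values
   drawn with replacement from the background pool, with the add-one
   estimator $p = (1 + \#\{S_{null} \ge S\})/(1 + n_mc)$. The null
   *conditions on the observed count* $n$: frequency information is
   deliberately excluded so the EA methods and the frequency baseline stay
   complementary and their consensus is informative. (An unconditional
   variant that also randomizes the count was considered and not
   implemented; conditioning is the behaviour all tests exercise.)

3. **Frequency.** The classical baseline: with $N$ counted mutations
   genome-wide, gene length $L_g$ and total coding length $L$, the exact
   binomial upper tail $P(X \ge n_g)$, $X \sim \mathrm{Bin}(N, L_g/L)$.

All three are one-sided by design: a driver is defined as a gene
accumulating *more* and *more impactful* mutations, so low counts and
downward EA shifts are never evidence. Benjamini–Hochberg correction is
applied within each method over the genes tested by it (the field-standard
choice; no specific correction is canonical for this analysis), and ranks
break p-value ties by descending sumEA (EA methods) or count (frequency),
then locus tag, so orderings are total and reproducible.

## Background construction

The default background is the **exhaustive enumeration** of every possible
coding SNV: each coding nucleotide times three alternate bases, annotated
exactly like observed data, with each gene's pool holding the EA scores of
its reachable missense changes. This is deterministic, exact, and cheap at
bacterial scale (3 SNVs per coding nucleotide; ~90,000 for the 30 kb test
genome, ~12.5 M for a 4.2 Mb genome). Random sampling
(`sample_background()`, default $10^5$ draws uniform over genomic position
× alternate base — the draw count is arbitrary and documented as such) is
retained for API parity and converges to the exhaustive pools; a custom
mutation set in any supported input format can replace both.

Backgrounds are **per-gene** by default: each gene's observed EA spectrum
is compared against what *that gene* can produce, which controls for
composition (a gene whose possible missense changes are all mild cannot be
called a driver merely for having mild mutations available). A
`genome_wide` scope is available. The mutation spectrum is uniform over
positions and alternate bases; transition/transversion bias and
context-dependent mutability are out of scope.

## Counting rules and edge cases

- A variant inside several overlapping genes annotates once per containing
  gene: statistics are per-gene, and numerator and denominator (background
  enumeration) apply the same duplication rule, so the comparison stays
  consistent.
- Duplicate identical rows within one strain collapse; the same
  substitution recurring in different strains counts once per strain by
  default (`collapse_recurrent = FALSE`) — recurrence across replicate
  lineages is treated as frequency signal.
- Frequency counts include nonsynonymous changes (missense, nonsense,
  start-loss, stop-loss); synonymous counting is a flag. EA statistics use
  scored missense only. Nonsense variants are excluded from EA statistics
  by default, with `nonsense_ea = "max"` scoring them 100 (premature stops
  as maximally disruptive) — the published EA convention defines scores
  for missense only, so both behaviours are one flag apart.
- Missense mutations without an EA entry stay in frequency counts, are
  dropped from EA statistics, and are reported; silent imputation would
  bias the sums.
- Genes with fewer scored missense mutations than `min_mut` (default 1)
  get p = 1 for the EA tests and no q-value; genes with an empty
  background pool are excluded and reported.
- Codon-1 changes that destroy the start codon (ATG/GTG/TTG) are
  `start-loss`; changes preserving a valid start are classified by their
  translated residues. Proteins are translated with straight table-11
  codon translation (no initiator-methionine special-casing) so per-codon
  translation, EA-table validation, and annotation agree with each other.

## Tunable parameters

| Parameter | Default | Meaning |
|---|---|---|
| `n_mc` | 10,000 | Monte-Carlo resamples for the EA_sum null; the attainable p floor is 1/(n_mc+1) |
| `min_mut` | 1 | minimum scored missense per gene to enter EA tests |
| `background_scope` | per_gene | background pool used by the EA tests |
| `nonsense_ea` | exclude | stop-gain handling in EA statistics |
| `collapse_recurrent` | FALSE | collapse cross-strain recurrence |
| `top_n` | 20 | list length for the consensus overlap |
| `seed` | NULL | seeds the Monte-Carlo nulls; one seed reproduces a run end to end |

## What the synthetic generator emulates

`make_fixture()` builds the entire study in code: a single-contig genome
of `n_genes` CDSs (ATG starts, TAA stops, random sense codons, both
strands, short intergenic spacers), an EA table drawn from
$100 \cdot \mathrm{Beta}(2, 2)$ per reachable missense substitution (a
broad unimodal impact spectrum centred at 50), and per-strain mutation
sets: neutral mutations uniform over all coding SNVs, plus seeded drivers
receiving `extra_mutations` distinct missense changes. The driver
`ea_bias` is the probability each extra mutation comes from the gene's top
EA quartile (complement: bottom quartile), so bias 1 is a true
impact-driver and bias 0 a high-count/low-impact decoy. Internal codons
avoid ATG/GTG/TTG so codon-1 classification is unambiguous in
strand-symmetry checks.

What it does **not** emulate — and what passing tests therefore cannot
show about real data: mutation-rate heterogeneity (hotspots, context
bias), selection on synonymous or regulatory sites, structural variants,
shared ancestry among clones from one lineage (mutations are drawn
independently per strain), and realistic EA score shapes for specific
protein families. The statistical engine is validated on this idealized
null; on real data the background model is the binding assumption.

## Numerical choices

- $D^+$ is computed by sorted ECDF evaluation over all pooled points
  (ties handled by right-continuity) and is checked exactly, to 1e-12,
  against a brute-force double-loop sweep.
- The EA_sum p uses the add-one estimator so p = 0 is impossible, and all
  observed sums are computed over *sorted* values so floating-point
  addition order — hence byte-level output — is identical across input
  formats.
- Empirical calibration of all three tests is verified on a 50-gene ~30 kb
  genome with 1,000 null replicates of 5 strains × 20 mutations (EA_sum
  null at `n_mc = 499`, at which the add-one estimator is exact at the
  nominal 0.05 level); rejection rates must sit inside or below the exact
  binomial 99% band around 0.05. Driver recovery is verified over 100
  seeded replicates (3 drivers, 10 extra mutations each, bias 1, top-6
  recovery for both EA methods; a bias-0 decoy must rank better under
  frequency than under EA_sum). These problem sizes complete in a few
  minutes on one CPU.
- Coordinates are 1-based inclusive everywhere internally (GenBank/VCF
  convention); GFF3 input is converted at the parser boundary by
  `rtracklayer`.
- Structure export writes track values into the PDB B-factor column
  (2-decimal fixed format, clamped to [0, 999.99]); undefined residues are
  flagged −1.00 and colored grey by the companion PyMOL script, keeping
  "no data" distinguishable from a true 0. A command script rather than a
  binary session file reproduces the visual state while remaining
  diffable and testable.

## Known limitations

- The GenBank reader covers the standard single-interval CDS dialect;
  compound (`join`) and fuzzy locations are skipped and reported, not
  modelled (eukaryotic splicing is out of scope).
- The asymptotic one-sided KS p-value is conservative at very small $n$;
  sensitivity for genes with a single observed mutation comes mostly from
  EA_sum and frequency.
- EA and ET scores are consumed, never computed; results inherit whatever
  biases the supplied score sets carry.
- The STRING enrichment step is an exported query payload, not an API
  call, by design.
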