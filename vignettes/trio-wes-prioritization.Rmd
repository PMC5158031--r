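---
title: "Trio exome prioritization with homozygosity mapping, depth CNV screening and truncation annotation"
author: "triorecess"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Trio exome prioritization: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(triorecess)
```

## Scope and model

`triorecess` prioritizes candidate variants for a severe autosomal
recessive phenotype from trio whole-exome data, in the specific regime
where the strict trio model can fail because the recorded father is not the
biological father. The pipeline is a composition of five deterministic
stages over a trio genotype table, a per-target depth table with a
reference pool, a transcript exon model and a protein domain map. Each
stage is an exported function; `run_pipeline()` composes them over files
and `report_from_trio()` over in-memory tables.

### Filter cascade

The consequence gate keeps `nonsense`, `missense`, `splice_site`,
`small_insertion` and `small_deletion`; everything else is `other` and
dropped. Consequence classes are input annotations: the package never
re-derives them from sequence, and third-party pathogenicity scores are
outside its scope.

The frequency gate passes a variant when **every known** database
frequency is at or below `maf_threshold` (default 0.005, inclusive: the
boundary value passes). A variant absent from a database passes that
database. The alternative — treating absence as frequency 0 is equivalent;
treating it as failure would discard precisely the novel ultra-rare
variants the analysis exists to find.

Two inheritance model families are tagged:

* **strict trio-recessive** — homozygous-alternate child with both parents
  heterozygous, or two passing variants in one gene with the trans
  configuration established through parental origin (one allele carried by
  each parent). A missing parental call is non-disqualifying by default
  (`missing_parent_compatible`), since genotype dropout should not veto a
  candidate; setting it to `FALSE` restores the hard requirement.
* **proband-only fallback** — homozygous-alternate in the child, or at
  least two passing heterozygous variants in one gene, parents ignored.
  Phase is unknowable without parental information, so any het pair in a
  gene qualifies; this deliberately over-calls compound heterozygotes and
  is the model to read when the consistency stage questions the pedigree.

Strict-trio homozygous candidates are a subset of proband-only candidates
by construction; the suite asserts this as a property.

### Homozygosity mapping

Runs of homozygosity are computed per chromosome over the proband's
genotype states. Missing calls neither break runs nor count as markers. A
run needs at least two homozygous markers; `roh_het_tolerance` (default 0)
allows embedded heterozygous calls for noisy genotypes, in which case runs
are maximal windows with at most that many embedded hets, trimmed to
homozygous endpoints. Span is measured marker-to-marker — first to last
homozygous marker — rather than padded toward flanking heterozygous calls:
conservative, and reproducible from the marker table alone. Regions
strictly longer than `roh_min_length_mb` (default 30 Mb, strict because the
criterion is "more than 30 Mb") are retained, and candidate variants are
annotated with the containing region. The mother's heterozygous fraction
inside each region is descriptive only: a carrier mother of an
identical-by-descent segment stays heterozygous at the population rate, but
the published procedure does not define a hard filter on it, so neither do
we.

### Depth-of-coverage CNV screen

For a sample with per-target depths $d$ and a reference pool, the
reference profile $m$ is the per-target median of the
library-size-normalized pool (each pool sample divided by its total before
the median — otherwise differing library sizes leak irreducible noise into
the median). The copy score at target $t$ is the double-normalized ratio

$$ s_t = \frac{d_t / \sum_u d_u}{m_t / \sum_u m_u}, $$

with diploid expectation 1.0, so the inclusive thresholds $s \le 0.5$
(suspected deletion) and $s \ge 1.5$ (suspected duplication) carry their
evident copy-number semantics. The score is invariant to rescaling any
sample's depths. Comparison is valid only when the Pearson correlation
between $d$ and $m$ strictly exceeds `cnv_corr_min` (0.97); a
zero-variance vector makes the correlation undefined and the comparison
invalid. Calls overlapping a population CNV with frequency above
`cnv_common_freq` (0.005) are excluded as common; unknown frequencies are
retained. There is deliberately no segmentation across adjacent targets:
the screen is per-target, as its published description is.

Two numerical caveats worth stating plainly. First, the thresholds sit
exactly at the expected score of a heterozygous event (0.5 and 1.5), so
for an unbiased score roughly half of true heterozygous single-target
events fall on the calling side of the threshold in any noisy replicate —
the screen is a red-flag generator, not a sensitive caller, and the
acceptance suite measures exactly that. Second, a copy-number change on a
target with very high capture intensity has enough leverage over a
200-target panel to pull the sample–pool correlation below the gate;
gate-failed screens return no calls by design.

The QC summary reports length-weighted fractions of targeted bases at or
above 10× and 25× and the length-weighted mean depth, treating each
target's mean depth as uniform across its bases.

### Mendelian consistency and parentage

Opposite homozygotes — child homozygous-alternate while a parent is
homozygous-reference — cannot occur under error-free Mendelian
transmission. The stage counts them per parent on autosomes only (X, Y, MT
excluded by name), in both directions, and compares father–son Y-marker
haplotypes (`compared`, `divergent`). The advisory flag raises when
`(father_count + 1) / (mother_count + 1) >= 20` or when at least 3 Y
markers diverge. The published analysis reported the counts and concluded
informally; the explicit pseudocount-ratio rule is this package's
formalization so the decision is reproducible and testable. The flag never
alters filtering — it tells the analyst which model family to believe.

### Truncation annotation

For a stop-gain at CDS position $c$, the stop codon is residue
$p = \lceil c/3 \rceil$. Shortening is reported as $L - p$ for an
$L$-residue protein (`reference_length` convention, default). The mutant
peptide actually has $p - 1$ residues, so the alternative
`peptide_length` convention reports $L - p + 1$; both are implemented
because published reports mix the two, and neither is asserted as the
biologically "correct" count. NMD escape follows the last-exon rule: a
stop in the last coding exon, or within `nmd_window_nt` coding nucleotides
(inclusive) upstream of the last exon–exon junction, escapes. The field
consensus window is 50–55 nt; the default is the conservative 50,
configurable to 55. Domain status partitions each 1-based closed residue
interval into `retained` (ends before the stop), `lost` (starts at or
after the stop — the residue replaced by the stop codon is counted as
lost) or `partial`.

The packaged GNAT1 map (350 residues) carries the literature-reported
functional sites; the packaged 8-exon transcript model sums to the true
1053-nt CDS but its interior exon boundaries are synthetic — only the
position of the last exon–exon junction matters to the NMD rule, and both
premature stops handled here (codons 302 and 321) lie in the last coding
exon regardless.

## The synthetic-data generator

`simulation_spec()` declares the study conditions; `simulate_trio()` and
`simulate_depth()` are byte-deterministic in its seed.

* **Genotypes.** 50,000 autosomal sites by default — the scale of a real
  trio exome variant table — placed uniformly over 22 autosomes with
  GRCh37-scale lengths; per-site allele frequencies Beta(0.8, 2), skewed
  rare. Parents are Hardy–Weinberg; the child receives one transmitted
  haplotype per parent. Inside planted homozygous-by-descent segments both
  child alleles copy the transmitted maternal allele; in `true_father`
  mode the father's transmitted haplotype is forced to the same allele
  (shared ancestry), which keeps zero-error trios exactly
  Mendelian-closed. In `unrelated` mode the observed father column and the
  Y haplotype are drawn independently of what the child inherited.
* **Planted variant.** A nonsense variant inside a planted segment,
  homozygous in the child, heterozygous in the mother, absent in the
  recorded father (carrier father under `true_father`), with an
  ExAC-style frequency of 8.3e-6 and unknown in the other databases.
* **Annotations.** Consequence classes drawn with realistic proportions
  (55% damaging classes overall); database frequencies equal the true
  allele frequency, with a database missing a variant with probability
  $(1-f)^{2000}$ — rare variants are often unknown, common variants are
  always annotated, as in real frequency databases.
* **Errors.** Symmetric genotype error: each call is replaced, with
  probability `genotype_error_rate` (default 1e-4), by one of the other
  two non-missing states uniformly. Inside a planted segment the child's
  heterozygosity rate is therefore the error model's `e/2`, not the
  population rate — asserted as a property.
* **Depths.** A shared lognormal capture-intensity profile (sdlog 0.9)
  truncated below at 0.5× — emulating a panel whose persistently weak
  targets were already removed by coverage QC — times a per-sample
  library-size factor, times planted copy ratios (proband only). Counts
  are negative binomial with `Var = mu * (1 + dispersion)` (dispersion
  0.05, i.e. 5% extra-Poisson variance; `poisson` available). Under these
  defaults the pool satisfies the 0.97 correlation gate with margin. The
  generator does **not** model GC waves, batch effects, low-coverage
  targets, segmental duplications, LD, recombination maps or read-level
  artifacts — passing tests show the inference chain is correct under its
  stated statistical assumptions, not that it is robust to everything real
  capture data does.

## Problem sizes and runtime

The test suite runs the full generator at 50,000 sites for the end-to-end
check, 20,000 sites for mapping and parentage checks, 100 seeded
200-target replicates for the CNV operating characteristics, 50 seeds for
Mendelian closure, and 100 random instances (≤ 200 elements) for
brute-force oracle equivalence of the run finder, interval containment,
filter cascade and threshold caller. These sizes keep the whole suite
around a minute on a laptop while staying in the same statistical regime
as a real exome.

## Known limitations

* The CNV screen's sensitivity for heterozygous events is intrinsically
  ~50% per target at the published inclusive thresholds (see above); it is
  a screen, not a caller, and no segmentation or B-allele integration is
  attempted.
* Proband-only compound-heterozygous calls cannot be phased and over-call
  by construction.
* The paternity statistic is advisory and deliberately simple; no
  likelihood-based kinship estimation (KING-style coefficients) is
  implemented.
* Multi-allelic sites are assumed decomposed into bi-allelic records
  upstream.
* The run-length convention (marker-to-marker) under-measures true segment
  length by up to one marker spacing on each side.
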