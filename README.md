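# triorecess

Trio whole-exome variant prioritization for autosomal recessive retinal
disease, built around the inference chain that identifies a homozygous
truncating variant in a sporadic rod-cone dystrophy trio when the recorded
pedigree cannot be trusted.

## The problem

A sporadic patient with a severe recessive phenotype is exome-sequenced
together with both unaffected parents. The standard analysis keeps rare,
protein-damaging variants that are homozygous (or compound heterozygous) in
the child and heterozygous in both parents. That strict trio model fails
outright when the recorded father is not the biological father: the causal
allele is then absent from his genotypes. `triorecess` implements the full
chain of evidence needed to recognize and resolve that situation:

1. **Filter cascade** — keep nonsense, missense, splice-site and small
   indel variants with minor allele frequency ≤ 0.005 in every annotation
   database that knows the variant (EVS, HapMap, 1000 Genomes, ExAC-style
   columns; a variant absent from a database is not discarded), then tag
   each survivor under the strict trio-recessive model and under a
   proband-only fallback that ignores parental genotypes.
2. **Homozygosity mapping** — maximal runs of homozygous calls in the
   proband; regions of more than 30 Mb mark likely autozygosity and
   localize the candidate; the carrier mother's heterozygosity across each
   region is reported as a cross-check.
3. **Depth-of-coverage CNV screen** — per-target copy score
   `s_t = (d_t / Σd) / (m_t / Σm)` against the median profile `m` of a
   reference pool (valid only when the sample–pool Pearson correlation
   exceeds 0.97), targets called as suspected deletion at `s ≤ 0.5` or
   duplication at `s ≥ 1.5`, then confronted with population CNV
   frequencies (> 0.005 excluded as common). Rules out a heterozygous
   exonic deletion mimicking homozygosity.
4. **Mendelian consistency** — counts of opposite homozygotes (child
   `hom_alt`, parent `hom_ref`) against each parent and Y-marker divergence
   between father and son; a lopsided father/mother ratio or ≥ 3 divergent
   Y markers raises an advisory non-paternity flag.
5. **Truncation annotation** — for a stop at codon *p* of an *L*-residue
   protein: shortening `L − p`, escape from nonsense-mediated decay when
   the stop lies in the last coding exon or within 50 nt upstream of the
   last exon–exon junction, and retained / partial / lost status for each
   functional site of the packaged GNAT1 map (350 residues; transducin
   β/γ, NLS, Mg²⁺, GTP/GDP, PDE6γ and rhodopsin binding sites).

A seeded synthetic-data generator (`simulate_trio()`, `simulate_depth()`)
produces all inputs with planted ground truth — Hardy–Weinberg parents,
Mendelian transmission, a planted autozygous segment carrying a homozygous
nonsense variant, an optionally unrelated father, overdispersed capture
depths with planted copy-number changes — so every stage is testable end to
end without patient data.

## Worked example

```r
library(triorecess)

spec <- simulation_spec(n_sites = 20000, father_mode = "unrelated", seed = 15)
sim <- simulate_trio(spec)
report <- report_from_trio(sim$trio, transcript = gnat1_transcript(),
                           domains = gnat1_domain_map())
print(report)
```

```
candidate_report
  strict trio-recessive candidates: 0
  proband-only candidates: 1 (1 homozygous, 0 compound het)
  large homozygous regions (> 30 Mb): 1
  paternity questioned (advisory): TRUE
  top candidate: GNAT1 3:50200000 nonsense (hom_proband_only), in_roh=TRUE
```

The strict trio model finds nothing (the unrelated father lacks the
allele); the proband-only fallback recovers the planted homozygous nonsense
variant, inside a detected > 30 Mb homozygous region, with the parentage
statistics flagging the inconsistency. Its truncation report:

```r
print(report$truncations[["3:50200000"]])
```

```
Truncation report: GNAT1 p.(321*)
  shortening: 29 aa (of GNAT1)
  NMD escape: TRUE
  ...
  GTP_321_323      lost
  PDE6G_306_310    retained
  RHO_311_328      partial
  RHO_340_350      lost
```

A stop at codon 321 of the 350-residue transducin α subunit removes 29
C-terminal residues, escapes nonsense-mediated decay (last coding exon),
destroys the 321–323 guanine-binding site, truncates one rhodopsin-binding
site and spares the PDE6γ site — the annotation pattern that separates this
truncation from the more damaging stop at codon 302 (48 residues lost,
PDE6γ site gone).

## The analysis workflow

Numbered drivers under `analysis/` run the whole study on simulated data
and write their tables under `results/`:

```sh
Rscript analysis/01_simulate.R   # inputs with planted truth
Rscript analysis/02_filter.R     # cascade + inheritance models
Rscript analysis/03_roh.R        # homozygosity mapping
Rscript analysis/04_cnv.R        # depth CNV screen + QC
Rscript analysis/05_consistency.R
Rscript analysis/06_protein.R    # truncation reports
Rscript analysis/07_report.R     # end-to-end ranked report
```

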