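---
title: "Methods: the two-step mitochondrial diagnostic pipeline"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: the two-step mitochondrial diagnostic pipeline}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mitotriage)
```

## The diagnostic problem

Mitochondrial disorders arise from pathogenic variants either in the
multi-copy mitochondrial genome (mtDNA) or in any of roughly 1,500
nuclear genes with a mitochondrial function, and their symptoms overlap
broadly with other neuromuscular diseases. `mitotriage` implements a
two-step diagnostic strategy for such patients as a reusable, testable
pipeline:

1. **mtDNA stage.** Deep sequencing of the whole mitochondrial genome is
   analysed for heteroplasmic point variants and small indels, large
   single deletions with exact breakpoints, and copy-number depletion.
   A known pathogenic point variant or a single large deletion solves
   the family; multiple deletions or depletion are treated as suggestive
   of a nuclear mtDNA-maintenance defect and escalate the family to the
   exome stage, as do negative results.
2. **WES stage.** Exome variant tables are filtered by allele frequency
   and predicted effect, then interpreted under the inheritance model
   dictated by family structure: consanguineous families and families
   with more than one patient (strategy A) are screened for autosomal
   recessive homozygous, compound heterozygous, and X-linked recessive
   variants, with runs of homozygosity (ROH) as a ranking signal; single
   patients from non-consanguineous families (strategy B) are
   additionally screened for heterozygous variants, restricted to a
   panel of OMIM dominant-disease genes, with de novo status resolved
   from parental genotypes.

Patients are stratified by the mitochondrial disease criteria (MDC): a
0-12 score over three capped sections (clinical; metabolic and imaging;
histology), binned as unlikely (0-1), possible (2-4), probable (5-7) and
definite (8-12). Group 1 contains the probable/definite patients,
group 2 the possible ones.

## Heteroplasmy model and cut-offs

Heteroplasmy is estimated as the mutant read depth over the total depth
at a site, which is unbiased under binomial sampling of reads from a
mixed mtDNA population. Two inclusive cut-offs are applied: 2% for
alleles in the packaged known-pathogenic table (recurrent disease
alleles such as m.3243A>G, m.11778G>A, m.14484T>C, m.13513G>A), and 5%
for all other positions and small indels. The inclusive reading was a
design choice: the cut-off phrasing does not state strictness, and
inclusiveness ensures a call at exactly 2% passes. The hypervariable
D-loop is excluded from calling; its bounds (16024-16569 and 1-576, the
standard control-region definition) are configurable because coordinate
conventions differ between laboratories.

## Deletion breakpoints from junction reads

Large deletions are detected from reads that fail to align contiguously:
both read ends are matched exactly against a doubled linear copy of the
reference (the doubling is the package's contract for the circular
genome; origin-spanning fragments are not modelled) and extended
maximally. A read whose 5' and 3' matches jointly cover it implies a
junction with `b5` = last retained base and `b3` = first retained base
after the deleted segment, so the deleted length is `b3 - b5 - 1` - the
unique convention consistent with all three recurrent breakpoint/size
pairs the pipeline is validated against (8482:13460 at 4,977 bp,
7462:15747 at 8,284 bp, 9514:15792 at 6,277 bp). Junctions flanked by
direct repeats are intrinsically ambiguous; calls are normalised to the
leftmost representation, which also merges reads that describe the same
molecule with the junction written at either repeat copy. Events need at
least `min_support` (default 3) junction reads; more than one distinct
event classifies the sample as carrying multiple deletions. The caller
is verified against a brute-force oracle that enumerates every
breakpoint pair consistent with a read on toy references.

Anchors default to 20 nt of exact match per side. With error-free reads
this places breakpoints exactly; with a non-zero simulated error rate,
reads whose errors fall inside an anchor are dropped rather than
rescued, which lowers support but never shifts a breakpoint.

## Copy number

qPCR quantities for a mitochondrial target (ND1) and a nuclear target
(B2M) are combined into an mt/nuclear ratio and expressed as a
percentage of the mean ratio of healthy controls. The depletion
threshold defaults to 35% of the control mean: depletion patients
present at 10-30% of controls, so the default separates them from the
null level (about 100%) with margin on both sides. It is configurable
because tissue and assay differences shift this boundary in practice.

## Runs of homozygosity

ROH detection operates on biallelic genotype tracks sorted by position:
maximal windows containing at most `het_tolerance` heterozygous calls
(default 0, as the synthetic tracks are error-free) whose physical span
between first and last marker reaches the cutoff (default 5 Mb) are
reported. Missing calls neither break nor extend a run, and runs are not
extrapolated beyond their terminal markers, a deliberately conservative
choice for sparse marker panels. Hemizygous calls count as homozygous so
X tracks of males need no special casing. The detector is verified
against brute-force window enumeration. Only the length criterion is
implemented; no population-frequency weighting of markers is applied.
ROH is used downstream as a ranking signal, not a hard filter - making
it a hard filter would discard legitimate compound heterozygotes in
consanguineous families.

## Variant filter cascade

The frequency filter keeps annotated variants with population allele
frequency strictly below 1% and keeps non-annotated variants unless
their in-house database frequency exceeds 5% (read as a strict "exceeds",
hence an inclusive 5% bound). The effect filter always retains nonsense,
frameshift and splice variants, removes synonymous and other classes,
and keeps missense variants when at least one of the four predictor
flags (PolyPhen-2, SIFT, PROVEAN, MutationTaster, consumed as upstream
annotations) is damaging; the combination rule is configurable because
no aggregation rule is prescribed by the predictors themselves. The two
filters commute, which is tested. ACMG classification is consumed as an
annotation (classes 1-5), not computed: a family is reported solved only
when a segregating candidate carries class 4 or 5, so class-3 candidates
remain variants of unknown significance. Segregation requires every
affected member to carry the mode-consistent genotype and no unaffected
member to do so, with one deliberate exception: a dominant variant
inherited from a parent flagged subclinical passes, mirroring families
in which follow-up investigation of a carrier parent revealed mild
symptoms. Compound heterozygotes that cannot be phased (missing
parents, both parents carriers) are retained with an `unphasable` flag
rather than dropped.

The dominant filter's panel restriction reproduces a known limitation:
de novo variants in genes not yet linked to dominant disease are
invisible to strategy B. This is intentional - the pipeline models the
strategy as practised, including what it would have missed.

## The synthetic cohort generator

The generator is first-class, tested code, not a fixture: it emits every
input the pipeline consumes, from a planted-truth manifest in which one
row is one family (the cohort counting unit). The packaged manifest
recreates a 117-family study cohort: 23 families with mtDNA defects
(9 LHON alleles, 7 m.3243A>G, one m.13513G>A, 6 single large deletions
including the common deletion in four patients), 57 with nuclear defects
(27 solved under strategy A, 30 under strategy B, 8 of them de novo),
and 37 defect-free filler families fixed by the published stage
denominators (42 strategy-A and 75 strategy-B units). Groups, MDC
scores, consanguinity, family sizes, MitoCarta membership and
inheritance categories are transcribed per family; multi-genic families
(three recessive genes in one family; a de novo dominant plus a
compound-heterozygous gene in another; a homozygous plus an inherited
dominant gene in a third) are planted as such.

Counting is per family row even where a family contains two patients;
this is the only reading under which the published totals (23 mtDNA
defects in 117 units) are arithmetically consistent, and it is flagged
here because per-patient counting would give 25. Two further details
are worth noting. First, the manifest stores the groups as printed;
patients with MDC score 5 appear in group 2 in the source tables even
though the scoring rule as stated would place them in group 1, so the
package never recomputes groups for the packaged cohort (the
`score_mdc()` default uses total >= 5 for group 1, configurable).
Second, mtDNA-stage MDC scores are not itemised in the source tables;
the manifest carries representative probable/definite values for those
families, which affects no reported quantity.

Simulation defaults are the study-like conditions the acceptance
arithmetic is computed under: 1000x mtDNA depth, 300 nt reads, 50
junction reads per deletion, zero base-error rate (configurable upward
for robustness experiments), 40 background exome variants per family
drawn from an anonymous gene universe disjoint from the causal genes,
eight qPCR controls, SNP markers every 100 kb with an 8 Mb embedded
homozygous run in consanguineous families and sub-cutoff decoy runs
(4.7 Mb) everywhere. Heterozygous markers are placed every 2-4.5 Mb in
the baseline tracks, so no background run can reach the 5 Mb cutoff by
construction. The mtDNA reference is a deterministic synthetic
16,569 nt sequence (the real reference sequence is not redistributed);
reference alleles at the known-pathogenic sites are pinned to the
canonical alleles and the three recurrent junctions are made
leftmost-unique so that planted and reported breakpoints coincide.

What the generator does *not* emulate - and what passing tests therefore
do not show about real data: sequencing chemistry and realistic
error/quality profiles, read alignment itself (the generator emits
aligned-coordinate pileups and unaligned junction reads), tissue-specific
heteroplasmy differences (tissue exists only as a label), real linkage
disequilibrium and ROH allele-frequency structure, and annotation noise
(population frequencies and predictor flags are planted, not queried
from live databases). Results on the packaged cohort demonstrate that
the decision logic reproduces the published arithmetic, not that the
callers would perform identically on raw sequencer output.

## Determinism and numerical choices

Every stochastic step derives a per-family, per-stage stream from the
single configuration seed via a string hash kept below 2^31, so
regeneration is byte-identical under the same seed while planted truth
is seed-independent. Percentages are displayed rounded half-up to whole
percent (so 27/40 prints as 68%), with raw numerators and denominators
always carried alongside. Ties and degenerate inputs are handled
explicitly: zero-depth pileup sites are skipped with a warning, an empty
cohort yields NA percentages, families whose stage errors are excluded
from all denominators with a warning (strict mode aborts instead), and
MDC section scores above 4 are capped with a warning.

## Problem sizes

The packaged runs are desk-scale by design: the full 117-family
pipeline completes in well under a minute, property suites use toy
references (up to 200 nt) against exhaustive oracles, ROH tracks up to
a few thousand markers, 100-replicate binomial simulations at depth
1000 for estimator unbiasedness, and 20 seeds for the false-positive
check on defect-free families.

## Known limitations

* Heteroplasmy of large deletions is not quantified from reads; as in
  practice, quantification is deferred to the qPCR-style copy-number
  ratio.
* The deletion caller requires junction-spanning reads with exact
  anchors; it does not model soft-clip rescue or split alignments from
  a real aligner.
* The ROH scorer implements only the length criterion, not the scoring
  scheme of interactive homozygosity-mapping tools.
* The MDC scorer consumes section scores; the itemised symptom
  checklist is out of scope.
* The dominant model requires the panel restriction; trio-based de novo
  discovery outside known genes is deliberately not implemented.
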