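# mitotriage

Two-step genetic diagnosis pipeline for patients with a probable or
possible mitochondrial disease, implemented as an R package with a fully
synthetic, planted-truth cohort so that the cohort-level results are
reproducible end to end without any external data.

## What it does

Mitochondrial disorders can be caused by pathogenic variants in the
mitochondrial genome (mtDNA) or in any of ~1,500 nuclear genes with a
mitochondrial function. The package implements the diagnostic strategy
of screening the mtDNA first and, if negative, analysing the exome under
the inheritance model dictated by family structure:

* **mtDNA stage** — point variants and small indels called from pileups
  with heteroplasmy *h* = mutant depth / total depth (2% cut-off for
  known pathogenic alleles, 5% otherwise, D-loop excluded); large
  deletions placed from junction-spanning reads by local matching
  against the reference, reported as breakpoints (b5, b3) with size
  b3 − b5 − 1 in leftmost representation; copy-number depletion from
  qPCR ND1/B2M ratios as percent of healthy-control mean. A known point
  variant or a single deletion solves the family; multiple deletions or
  depletion escalate it to WES.
* **WES stage** — variants filtered by population allele frequency
  (< 1%; non-annotated kept unless in-house frequency exceeds 5%) and
  effect (truncating always kept; missense kept with ≥ 1 damaging
  predictor call), then interpreted as AR-homozygous / compound-
  heterozygous (in trans) / X-linked candidates for consanguineous or
  multi-patient families (strategy A, with ≥ 5 Mb runs of homozygosity
  as a ranking signal), plus OMIM-panel-restricted dominant and de novo
  candidates for single patients of non-consanguineous families
  (strategy B). A family is solved by a segregating candidate of ACMG
  class 4/5.

A synthetic cohort generator recreates a 117-family study cohort
(23 mtDNA defects, 57 nuclear defects, 37 unsolved) from a packaged
manifest, including heteroplasmic pileups with binomial read sampling,
deletion junction reads at stated breakpoints, qPCR depletion records,
consanguineous ROH structure, and per-family exome tables whose planted
causal variants survive the filter cascade while background variants do
not.

## Worked example

```r
library(mitotriage)

manifest <- load_manifest()          # packaged 117-family cohort
report <- run_pipeline(manifest, sim_config(seed = 1))
print(report)
```

```
Two-step diagnostic pipeline report
  families analysed:     117
  overall yield:         68% (80/117)
  mtDNA stage:           20% (23/117)
  WES stage:             49% (57/117)
  WES strategy A:        68% (27/40)  [group 1: 65% (17/26), group 2: 71% (10/14)]
  WES strategy B:        56% (30/54)  [group 1: 59% (22/37), group 2: 47% (8/17)]
  de novo (strategy B):  15% (8/54)
  mtDNA breakdown:        LHON 39% (9/23), m.3243A>G 30% (7/23), single deletions 26% (6/23)
  MitoCarta-absent genes (group-1 WES): 31% (13/42)
```

Reading the output: 23/117 families are solved at the mtDNA stage (all
group-1 patients — LHON alleles, m.3243A>G, m.13513G>A and six single
large deletions); the remaining 94 proceed to the exome stage, which
solves 57 more, for an overall yield of 80/117. Among the group-1
families solved by WES, 13 of the 42 causal genes are absent from the
MitoCarta panel — the fraction a MitoCarta-based gene panel would have
risked missing.

Individual stages are exposed as ordinary functions, e.g.

```r
fam <- manifest[manifest$family_id == "MT020", ]      # common deletion
mt  <- generate_mt_reads(fam, sim_config(seed = 1))
detect_deletions(mt$reads, synthetic_mt_reference())
#>      b5    b3  size supporting_reads single_or_multiple
#>    8482 13460  4977               50 single
```

A thin CLI is installed with the package
(`system.file("cli", "mitotriage", package = "mitotriage")`):

```sh
Rscript inst/cli/mitotriage run --seed 1 --outdir out/
```

which writes per-family outcomes (`families.tsv`), the yield tables
(`report.json`), ROH BED files and a per-stage log.

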