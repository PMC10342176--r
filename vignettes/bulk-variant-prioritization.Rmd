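---
title: "Prioritizing causal variants from mutant/wildtype bulk sequencing"
author: "bulkscan"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Prioritizing causal variants from mutant/wildtype bulk sequencing}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
suppressMessages(library(bulkscan))
```

## The problem

A mutagenized plant line segregates a recessive phenotype 3:1 after
selfing. Two DNA pools are sequenced: a *mutant bulk* of plants showing the
phenotype and a *wildtype bulk* of phenotypically normal siblings. At the
causal locus the mutant bulk is fixed for the mutant allele (every plant is
homozygous), while the wildtype bulk carries it at a predictable low dose.
Everywhere else, induced background variants segregate independently of the
phenotype. bulkscan automates the workflow that turns this contrast into a
short, ranked candidate list: hard filtering of each bulk's variant calls,
restriction to damaging consequence classes, subtraction of calls shared by
both bulks, and an exact-binomial consistency score of each surviving
candidate against the allele-read fractions Mendelian segregation predicts.

Classical SNP-index scans (sliding-window alternate-read fractions) are
also provided as a comparison statistic via `snpIndex()`. On this design
they tend to drown in heterozygous background loci — which is precisely why
the call-level subtraction plus per-candidate read re-examination is the
primary path.

## The segregation model

For a monogenic recessive locus in a selfed family (progeny ¼ mm, ½ Mm,
¼ MM; phenotype mutant iff mm), with equal per-plant contribution to the
pool:

* mutant bulk: expected mutant-allele read fraction **1**;
* wildtype bulk, known composition (h heterozygotes among n plants):
  **h/(2n)** — e.g. 3 of 6 gives 0.25;
* wildtype bulk, unknown composition: phenotypically wildtype progeny are
  carriers with probability 2/3, giving **(2/3)·(1/2) = 1/3**.

`expectedAltFraction()` implements exactly this; a known heterozygote count
overrides the 1/3 prior because direct genotype knowledge beats the family
expectation. Phenotype segregation itself is checked with
`chisqSegregation()`, a Pearson goodness-of-fit test with 1 df (classes − 1);
Yates' continuity correction is off by default, matching common practice
for 3:1 tests, and available as a flag.

## The consistency score

For each candidate the observed allele depths of *both* bulks are tested
against the model: the mutant bulk against fraction 1, the wildtype bulk
against its design expectation. `binomialConsistency(k, n, f)` is the exact
two-sided binomial p-value by minimum-likelihood summation — the total
probability of all outcomes no more likely than the observed one. We use
this definition rather than doubling one tail because it stays well defined
for the asymmetric expectations this design produces (f = 0.25, 1/3, 0.99).
The expectation is clamped to `[errorRate, 1 − errorRate]` (default error
rate 0.01) so that f = 1 cannot be refuted with certainty by a single
errored read: sequencing error exists, and "all reads mutant" can never be
literal. The two p-values are Fisher-combined,
`−2(log p_mut + log p_wt)`, chosen over min-p for smoothness; both
components are reported alongside. Candidates whose mutant-bulk alternate
fraction falls below 0.9 (configurable) are flagged *incompatible* — a
causal recessive site must be nearly homozygous in the mutant bulk — and
rank after all unflagged candidates. Remaining ties break by effect
severity (frameshift > stop-gain > missense; a frameshift is the most
disruptive class an induced point lesion commonly produces), then genomic
order, so output is deterministic.

## Filtering semantics, and why the subtraction works

`hardFilter()` applies `minDP` (6), `minGQ` (0), `minQD` (2) and, to
heterozygous calls only, a minimum *major-allele balance* `minAB` (0.8):
a het call passes only when its read support is strongly skewed. Balanced
heterozygous calls — the overwhelming majority of segregating background
loci, and the causal site in the wildtype bulk — are removed. This is the
single most consequential convention in the package, because it controls
whether the wildtype bulk's low-fraction causal call survives into the
subtraction: upstream hard-filter implementations document this setting
only loosely, so the rule is stated here explicitly and is overridable.
"Presence" for `bulkSubtract()` then means a passing filtered call, *not*
read-level support. The causal variant therefore survives subtraction (its
wildtype call is absent or filtered) even though roughly a quarter of the
wildtype bulk's reads carry it; those reads are deliberately re-examined
afterwards by `scoreCandidates()`, which takes a site-evidence table of raw
per-bulk depths — the automated stand-in for inspecting each candidate's
reads in a genome viewer. When no such table is supplied the evidence is
assembled from the raw (pre-filter) call sets, with candidates lacking
depths in either bulk reported unranked as `no_evidence` rather than
silently scored.

Absent QD/GQ/AD fields pass their rule permissively (with a logged count):
a threshold of 0 on genotype quality in the reference settings signals
permissive intent, and dropping records for missing annotations would bias
against sparsely annotated callers.

## Deletion scanning

Large homozygous deletions leave unambiguous signals: windows of zero
sequencing coverage, and runs of consecutive genes with zero expression.
`detectDeletions()` reports maximal runs of coverage windows at or below an
absolute threshold (default 2 reads — a hard low threshold is the faithful
automation of "no reads visible"), merging runs separated by at most
`maxGap` bases and keeping spans of at least `minLength` (default 50 kb,
sized to suppress single-window dropouts while catching events in the
several-hundred-kb range). Boundaries are reported at window resolution; no
split-read refinement is attempted because the input is a windowed track.
`deletedGenesFromExpression()` is the RNA-side analogue: runs of at least
`minRun` (default 3) consecutive silent genes (expression ≤ 0.1 units).
Genes missing from the expression table break a run — absence of data is
not evidence of silence. `genesInInterval()` and `countLocusIdRange()`
enumerate the affected loci, collapsing splice-variant suffixes so each
locus counts once.

## Coding consequences

`applyVariantToCds()` maps a variant's REF footprint through the gene
model's CDS segments (reverse-complementing on the minus strand), refusing
edits that straddle an intron boundary, and `translateAndClassify()`
translates both alleles with the standard nuclear code. Protein length
excludes the stop codon, so a 1734 bp CDS ending in a stop encodes
1734/3 − 1 = 577 residues. Frameshift is decided purely by the length
change mod 3; otherwise premature stops, lost stops and substitutions are
distinguished on the translated products. Only the primary transcript per
gene is used, and UTR/splice-site classes are not guessed: anything outside
the CDS reports `non_coding`. `syntheticTruncationCds()` constructs, from
scratch, a synthetic 1734 bp CDS together with a frameshifting 4 bp
deletion whose shifted frame meets its first stop after residue 380 — a
fully reproducible stand-in for a real truncated allele whose genomic
coordinate is not public.

## What the simulator emulates — and what it does not

`simulateBulkExperiment()` generates: a selfed family (genotypes ¼/½/¼,
bulks assembled by phenotype, wildtype-bulk carriers either forced or drawn
conditional on phenotype); a causal frameshifting deletion mid-CDS;
background variants, half of them shared between bulks (homozygous
line-vs-reference differences) and the rest bulk-specific heterozygous
sites at alternate fraction 0.5 × carrier-fraction with the carrier
fraction drawn per variant — deliberately creating the "too many
heterozygous loci" nuisance that defeats naive index scans; per-site,
per-bulk depths Poisson(`meanDepth`) with binomial alternate reads at the
error-adjusted allele fraction; and a caller model that emits a record at
≥ 2 alternate reads and fraction > 0.2, heterozygous below 0.8 and
homozygous above. The default scenario — 2 Mb genome, 200 genes, 1000
background variants, 50% shared, 30× depth, 1% error, bulks of 4 mutant
and 6 wildtype plants with 3 heterozygotes — mirrors the experimental
design the package targets while running in well under a second, so
hundred-seed recovery studies stay interactive.

Real data differ in ways the simulator does not model: mapping artefacts
and repeat-mediated false calls, indel representation quirks, depth
autocorrelation along the genome, contaminated or mis-phenotyped plants,
and annotation errors. Passing recovery tests therefore demonstrates the
*logic* of the workflow — filtering semantics, subtraction bookkeeping,
score calibration — not robustness to every artefact of a real run; the
hard filters exist precisely because real callsets are noisier than this.

## Numerical and design choices

* Coordinates: VCF/GFF3 are 1-based inclusive, bedGraph 0-based half-open;
  all conversion happens at the I/O boundary (`readCoverage()` returns
  1-based ranges) so interval arithmetic never mixes conventions.
* Multi-allelic records are decomposed per alternate allele, never
  dropped; indels are taken as the caller left them (no re-normalization),
  because the workflow consumes caller output as-is.
* Consequence strings are matched case-insensitively across both common
  dialects ("missense_variant" / "missense variation").
* Two-sided binomial ties are accepted within a 1 + 1e−7 relative
  tolerance, the standard guard against floating-point ties in
  minimum-likelihood summation.
* `binomialConsistency` with zero usable depth returns p = 1 flagged
  `no_evidence` instead of erroring: no data is perfect consistency with
  anything, and the flag keeps such candidates out of the ranking.
* The report, batch script and manifest contain no timestamps; identical
  inputs and configuration reproduce byte-identical output.
* Validation problem sizes: recovery studies in the test-suite and the
  acceptance script use 100 seeds of the default scenario for causal-
  variant ranking and 100 seeds of a planted 300 kb deletion (interval
  800,000–1,100,000 of the 2 Mb genome) for the coverage scan; the
  segregation test's type-I error is checked on 10,000 simulated null
  families of 100 plants. These sizes give Monte-Carlo error small enough
  for the stated bounds while keeping a full validation run in minutes.

## Known limitations

* Only the monogenic-recessive, selfed-family design is implemented; the
  `BulkDesign` inheritance field is an extension point, not a promise.
* The wildtype-bulk expectation assumes equal per-plant DNA contribution;
  unequal pooling would shift the expected fraction and is not modelled.
* Coverage-based deletion boundaries are window-resolution; users wanting
  base-pair breakpoints need split-read evidence from an SV caller, whose
  output this package does not consume.
* The consequence predictor handles one (primary) transcript per gene and
  does not call splice-site or regulatory effects.
* The per-line printed p-value ranges of the motivating experiments are
  not reproducible from published counts (the per-line tallies were not
  printed); pooled-count statistics are computed instead, and the observed
  one-in-six wildtype read fraction versus the quarter-dose design
  expectation is reported as given — the package surfaces both expectation
  and observation without forcing agreement.
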