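---
title: "Methods: pedigree-aware rare-variant discovery, expression follow-up, and survival cutoff scanning"
author: "famvarscan"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: pedigree-aware rare-variant discovery}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(famvarscan)
```

famvarscan reimplements, as a tested and reusable pipeline, the analysis
pattern of a familial rare-variant study in neuroblastoma: exome variants
from affected relatives are filtered down to rare coding candidates, the
survivors are tested for segregation with disease across the family, a
candidate's coding effect is named, and the gene's expression is followed
up against MYCN copy-number status and overall survival. Because studies
of this kind rarely deposit raw exomes or cohort tables, the package
ships a synthetic-cohort generator that emits every input format the
pipeline reads, with the statistical structure the analysis assumes.
Everything below is the package's own account of the methods and of the
design decisions taken where the design was genuinely open.

## Kinship and expected sharing

Kinship is computed by the standard recursive tabular method over a
topological order of the pedigree. For a founder $i$, $\varphi(i,i) =
\tfrac12$; for a non-founder with parents $f$ and $m$, $\varphi(i,i) =
\tfrac12\,(1+\varphi(f,m))$ and, for any non-descendant $j$,
$\varphi(i,j) = \tfrac12(\varphi(f,j)+\varphi(m,j))$. Founders are
assumed mutually unrelated and non-inbred — the standard assumption, and
the one required for the familiar "second cousins share about 3% of
their genome" figure to hold: second cousins (a pair sharing only one
great-grandparental couple) have $\varphi = 1/64$, relatedness $r =
2\varphi = 1/32 = 3.125\%$. Note the phrase "second degree cousins" in
the clinical literature is ambiguous; we interpret it as second cousins
because first cousins once removed would share $6.25\%$, not
$\sim 3\%$. The recursion is cross-checked in the tests against an
independent path-counting oracle ($\sum (\tfrac12)^{n_P+n_Q+1}(1+F_A)$
over node-disjoint ancestral path pairs).

The gene-dropping simulator transmits alleles down the pedigree with
probability $\tfrac12$ per meiosis, independently across meioses and
replicate loci, and reports two different sharing statistics that are
easy to conflate:

* **joint carriage** of one specific allele planted heterozygously in a
  founder — for a second-cousin pair this is a six-meiosis chain,
  $(\tfrac12)^6 = 1/64 \approx 1.6\%$;
* **IBD sharing fraction** — every founder allele is labelled uniquely
  and the shared fraction (0, $\tfrac12$ or 1 per locus) is averaged;
  its expectation is $r$, so for second cousins $1/32 \approx 3.1\%$.

The "3% shared" figure quoted in study-design discussions is the second
statistic, and it is the one the acceptance script recomputes; the first
is what matters when asking whether two relatives both inherited one
particular mutation. The two agree only for pairs connected through a
single common ancestor.

Penetrance is the affected fraction among carriers, $f =
k_\text{affected}/k_\text{carriers}$; 5 affected among 16 carriers gives
$f = 0.3125$, reported as 31%.

## The filtering cascade

The cascade mirrors the discovery design: keep variants carried by every
sequenced affected member, drop variants seen in any sequenced healthy
relative, keep the rare or novel, keep the consequence classes of
interest (missense by default), then test segregation across the whole
family. Semantics worth stating precisely:

* **Missing genotypes are asymmetric.** Missing in an affected sample
  fails the sharing test; missing in an unaffected sample does *not*
  exclude the variant. A candidate is never promoted, and never
  discarded, on absent evidence.
* **Rarity is strict**: novel (no dbSNP id), or an annotated minor
  allele frequency strictly below the threshold (default 0.01). A
  catalogued variant with no MAF annotation is classed known-common:
  presence in a catalogue counts as "already described" unless rarity is
  documented. The two output sets partition the input exactly.
* Coordinates are 1-based VCF convention; sites are biallelic after
  multiallelic decomposition; indels are out of scope (the cascade
  analyses SNVs). PolyPhen-2/SIFT fields are pass-through annotations
  used for reporting only, never recomputed.
* The three pure per-variant predicates (absent-in-unaffected on a fixed
  sample set, rarity, consequence) commute with each other and with the
  sharing filter; the shipped order is the narrative order, not a
  mathematical requirement. Each stage logs in/out counts so the cascade
  is auditable on any input.

Segregation flags — never silently drops — variants not carried by every
sampled affected member, and reports penetrance over all sampled
carriers, since incomplete penetrance is the norm in this disease.

## Coding effect

CDS position $p$ sits in codon $\lfloor (p-1)/3 \rfloor + 1$ at offset
$((p-1) \bmod 3) + 1$; codons are translated with the standard genetic
code only. HGVS output uses the simplified substitution grammar
(`c.802C > T`, `p.R268C`) without reference-sequence prefixes, matching
how such mutations are quoted in clinical papers. Genomic-to-CDS mapping
walks exons in transcription order — reversed for a minus-strand gene —
and subtracts the 5' UTR offset; intronic and UTR positions return
tagged designations, not errors. Allele projection across strands is the
Watson–Crick complement, so a forward-strand G/A site is a C/T change on
a reverse-strand transcript. Round-tripping CDS↔genome on both strands
is property-tested on packaged toy transcripts.

## qPCR expression analysis

Reference stability follows the geNorm logic: for candidate reference
gene $j$, $M_j$ is the mean over other candidates $k$ of the standard
deviation across samples of $Ct_k - Ct_j$ (the log2 expression ratio
under 100% amplification efficiency); the highest-$M$ gene is dropped
iteratively until the requested number of references remains. Only the
$M$-ranking with iterative exclusion is implemented; the pairwise
variation $V_{n/n+1}$ cut-off of the full protocol is not. $M$ is
invariant to per-sample loading shifts by construction.

Quantification is ΔΔCt with 100% efficiency (factor 2 per cycle) — no
standard curves are modelled — normalizing by the arithmetic mean of the
reference Cts (equivalent to the geometric mean of linear quantities):
$\Delta Ct_s = Ct_{\text{target},s} - \overline{Ct}_{\text{refs},s}$,
and the relative quantity is $2^{-(\Delta Ct_s - \Delta
Ct_\text{cal})}$ with the least-expressed detected sample as calibrator,
so quantities are arbitrary units relative to the least expressed sample
and the minimum over expressed samples is exactly 1. "Expressed" means
the target was detected at or below a configurable maximum Ct (default
40 cycles); no instrument-specific cut-off is assumed beyond that.

Association with MYCN status reports the three-way grouping (amplified /
gain / single copy) but tests amplified vs single copy only: Fisher's
exact test (two-sided, by hypergeometric tail summation) on positivity,
and Mann–Whitney plus Welch's unequal-variance $t$ on the quantities of
expressed samples. All tests are two-sided; sidedness is rarely stated
in the source literature, and two-sided is the conservative default. The
Mann–Whitney test is exact (enumeration) when the combined sample size
is at most 10 without ties, and uses the tie-corrected normal
approximation otherwise; an optional log2 transform is exposed for the
$t$ test since quantities are log-normal-ish. Degenerate inputs are
defined rather than fatal: two constant equal groups give $t = 0$, $p =
1$.

## Survival cutoff scanning

Kaplan–Meier estimation and the log-rank test are delegated to the
survival package (product-limit estimator; observed-minus-expected
chi-square with hypergeometric variance, 1 df). The "scan" cut-off
modus, popularized by web survival tools, is reimplemented locally:
candidate cutoffs are midpoints between consecutive sorted distinct
expression values; only cutoffs leaving both groups at least
`min_group_size` members (default 8 — a guard against degenerate
1-vs-rest splits on an 88-sample cohort; web tools do not publish their
floor) are eligible; each is scored by the log-rank $p$ of expression
$\geq$ cutoff versus below, and the argmin is chosen, with ties broken
towards the most balanced split for determinism. The high group is
defined as expression at or above the cutoff so that "higher expression
is worse" reads directly off the output.

Two caveats are built into the output rather than left to the reader:

1. **Multiplicity.** The scanned minimum $p$ is the minimum of many
   correlated tests and is anti-conservative under the null; the test
   suite demonstrates this over 200 null simulations, and every scan
   result carries a multiplicity warning string.
2. **Localization spread.** Even with a genuine threshold effect
   (hazard ratio 3 at $n = 88$), the argmin of a maximally selected
   log-rank statistic has an irreducible sampling spread of a few
   candidate ranks around the generative threshold (median rank error
   about 2 in our simulations, with occasional global misses). A single
   scan's chosen cutoff should therefore be read as approximate; the
   direction of the effect is far more stable than its location (the
   high-group-worse call is correct in $\geq 95\%$ of simulated runs).

The stratified report runs one scan per stratum of the published
analysis pattern — all patients; MYCN-not-amplified; relapse or
progression (all, and MYCN-not-amplified); localized stages with no MYCN
amplification; metastatic — recording empty or unscannable strata as
not-evaluable rows.

## The synthetic cohort

The generator is the package's stand-in for unavailable raw data, and
its defaults are fixed study conditions, not tuning knobs:

* **Family**: a 22-member, four-generation pedigree descending from one
  founder couple, with five affected members of whom two (E5, E10) are
  second cousins; the published family's exact topology is only
  available as a figure, so this fixture is faithful by construction in
  its counts and key relationships rather than a literal copy.
* **Variant table**: unlinked background SNPs with founder genotypes
  drawn binomially at their allele frequency and gene-dropped to
  descendants; consequence classes follow the proportions of the
  shared-variant column of the study's whole-exome statistics table;
  about 96% of background variants are catalogued common SNPs, and a
  fifth of the remainder are catalogued-but-rare. One causal rare
  missense variant is planted heterozygously in a founding
  great-grandparent. Affection is then reassigned as carrier ∧
  Bernoulli($f$) with $f = 0.3125$ by default (the 5/16 penetrance
  figure) and phenocopy rate 0, so every affected member is a carrier
  and the planted variant segregates by construction. Linkage
  disequilibrium, site-frequency-spectrum realism and sequencing error
  are deliberately absent: the cascade operates per variant, and none
  of these would change what it computes.
* **Expression cohort**: 76 patients; MYCN status proportions 20/15/65%
  (amplified/gain/single copy); detection probabilities 0.60/0.30/0.12
  by status, giving roughly 24% overall positivity; detected samples
  draw log2 quantities from status-specific normals two log2 units
  apart (amplified vs single copy, sd 0.8). Ct values embed a shared
  per-sample loading shift, three stable reference genes, and one
  deliberately noisy decoy reference that the geNorm ranking should
  reject — which it does in ≥95% of simulated runs.
* **Survival cohort**: 88 samples; log2 expression from a two-component
  mixture (a not-expressed mode at 0 and an expressed mode at 3, sd
  0.7, 45% expressed) with the true threshold at the component
  boundary ($2^{1.5}$); exponential event times at 0.008/month,
  multiplied by a hazard ratio of 3 at or above the threshold;
  independent exponential censoring at 0.004/month; stage, relapse and
  MYCN tags drawn independently. The bimodal marker reflects the
  expressed/not-expressed character seen in the qPCR cohort.

Determinism is part of the contract: identical configuration and seed
give byte-identical output files, and every simulated child genotype is
Mendelian-consistent with its parents (both are tested exhaustively).
Because incomplete penetrance makes multi-case families rare per
replicate, the discovery driver in `analysis/` emulates study
ascertainment: seeded replicates are screened until the family presents
at least two affected members, and the screening count is reported.

What passing tests on this generator do **not** show: performance on
real exomes (alignment and calling artefacts, LD, population
stratification, relatedness misspecification), real qPCR efficiency
variation, or real survival-cohort covariate structure. The generator
validates the logic and the statistics of the pipeline, not the
upstream measurement process.

## Numerical choices and problem sizes

Percentages are reported to one decimal in tables (full precision is
kept internally); integer-percent comparisons use nearest-integer
rounding. The MAF bound is strict (<). Monte-Carlo checks in the test
suite use 2×10^5 gene-dropping replicates (agreement with $r$ within 3
Monte-Carlo standard errors), 100-run batches for recovery and
direction properties, and 200 null simulations for the
anti-conservativeness demonstration — sizes chosen so the whole suite
stays in the minutes range on a single core while keeping the Monte-
Carlo error well below the asserted margins. Scan ties are broken
deterministically (most balanced split, then lowest cutoff). Degenerate
inputs (constant expression, empty strata, zero-event groups, empty
variant tables) return tagged results or precise errors rather than
propagating NaN.

## Known limitations

Kinship is autosomal only (no X-linked variant); inbred founders are not
modelled; the full geNorm pairwise-variation protocol and probe
efficiency calibration are out of scope; the scan reports chi-square
log-rank $p$ values (a permutation mode for small strata would be a
natural extension); and the cutoff scan's localization spread at
realistic sample sizes (see above) means its chosen cutoff is an
estimate with several-rank uncertainty, not a sharp threshold.
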