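---
title: "Prioritizing germline variants in cancer-prone families"
author: "FamVarPrior"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Prioritizing germline variants in cancer-prone families}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(FamVarPrior)
```

## The problem

Whole-genome sequencing of a few members of a cancer-prone family yields
on the order of 10^5 germline variant calls per family, of which at most
a handful can plausibly explain a dominant predisposition. FamVarPrior
implements the standard funnel used in familial cancer studies — here
motivated by familial Hodgkin lymphoma, a B-cell malignancy with strong
familial clustering but few known predisposing genes — as a tested,
reusable package: call-quality and population-frequency filtering,
pedigree-based segregation filtering under a dominant model, separate
prioritization cascades for coding and regulatory non-coding variants,
screening against cancer gene panels, and tiered per-family reports.
Because real familial sequencing data are almost never shareable, the
package also ships a synthetic-cohort generator that plants a dominant
causal variant in pedigrees shaped like a real three-family study, so
every stage can be exercised and benchmarked end to end.

## The filter funnel

Stages run in a fixed order; each is a pure per-variant predicate, so the
*survivor set* is order-invariant even though per-stage counts are not.

1. **Call quality.** Site quality strictly above 20 and coverage strictly
   above 5x. Indels additionally need the caller's internal PASS flag
   (they come from a dedicated indel caller whose internal filters are
   authoritative). A missing metric fails the variant.
2. **Strand bias.** An SNV needs at least one alternate-allele read on
   each strand in at least one *carrier* sample. Indels skip this stage.
   When no carrier has strand counts at all, the default is to pass with
   a warning (configurable to fail) — dropping calls for missing
   metadata would silently bias the funnel.
3. **Population frequency.** `max(MAF_1000G, MAF_ExAC-nonTCGA) < 0.001`.
   A missing frequency counts as 0: a variant absent from both reference
   panels is maximally rare, and treating absence as commonness would
   discard exactly the novel variants the analysis is after.
4. **Segregation (dominant model).** Every genotyped case must carry at
   least one alternate allele (homozygous carriers count), every
   obligate carrier — an unaffected relative who must carry the variant
   by pedigree position — must carry it, and at most
   `maxControlCarriers` controls may carry it (default 0). The
   published description of this step ("the probability of an individual
   being a Mendelian case or true control") is not a formal model; we
   implement it as this deterministic carrier-pattern policy and expose
   `maxControlCarriers` and the missing-genotype handling
   (permissive/strict) as the knobs that emulate phenocopy and
   penetrance tolerance. Under permissive handling (default) a missing
   genotype is simply uninformative; under strict handling a missing
   case genotype fails the variant.

## The coding arm

Variants that survive the funnel split by functional class:
non-synonymous SNVs take the missense path; stopgain SNVs and frameshift
indels the nonsense path.

* **CADD PHRED > 10** (strictly; missing CADD fails): roughly the top 1%
  most deleterious substitutions genome-wide.
* **Conservation**: GERP > 2.0, PhastCons > 0.3, PhyloP >= 3.0 (note the
  one non-strict bound). The cascade is *conjunctive over present
  scores*: any present score missing its threshold fails the variant,
  but a variant with no conservation annotation at all is
  `not_applicable` and treated as passing, flagged in reports. This
  leniency is deliberate — conservation tracks have incomplete coverage,
  and a hard requirement would silently discard sparsely annotated
  candidates (the published candidate tables print no conservation
  columns at all).
* **Missense consensus**: ten effect predictors (SIFT, two PolyPhen-2
  models, LRT, MutationTaster, MutationAssessor, FATHMM, MetaSVM,
  MetaLR, PROVEAN) vote; the variant passes when at least 60% of the
  *available* calls are deleterious, with a floor of five available
  tools. The denominator is available rather than 10 because predictor
  coverage is incomplete; the floor stops one or two stray calls from
  deciding. With all ten available this reduces to `votes >= 6`.
* **Nonsense votes annotate, never exclude**: eight predictors (DANN,
  MutationTaster, FATHMM-MKL, FATHMM-XF, ALoFT, EIGEN, EIGEN-PC,
  PrimateAI) are tallied into a label — `no_support` (0),
  `supporting(k)` (1–4), `majority_pathogenic` (>= 5) — but truncating
  variants of uncertain significance are retained on CADD and
  conservation alone. The exact mapping from votes to the labels of
  commercial aggregators is proprietary; these labels are a declared
  package convention.
* **Intolerance ranks, never cuts**: retained candidates are ordered by
  descending intolerance-source count (n/3), then descending CADD, then
  descending predictor votes, then ascending (chrom, pos) — a total
  order, so ranking is permutation-invariant and ties are impossible.
  The per-source numeric thresholds behind the three intolerance flags
  are produced upstream, on the annotation side; the package consumes
  the flags.

## The non-coding arm

UTR and gene-flank variants are windowed against a transcript-bounds
gene model: 5'UTR and upstream variants within 1 kb of the transcription
start, and 3'UTR and downstream variants within 1 kb of the
transcription end, strand-aware (upstream of a minus-strand gene lies at
higher coordinates). The 1 kb window is inclusive at exactly 1000 bp.
Retention requires CADD > 10 plus region-appropriate regulatory
evidence: a predicted miRNA target site for the 3' side; a promoter,
enhancer, super-enhancer or TFBS for the 5' side. CpG-island membership
is recorded as a flag but is not a retention criterion (mirroring the
selection rule of the motivating study, which lists it as annotation
only); the same holds for chromatin-state columns, which are carried
into reports but never gate retention. 3'-side candidates rank by
ascending mirSVR (more negative = stronger predicted down-regulation),
5'-side candidates by the number of regulatory categories hit.

All interval work is 0-based half-open internally; VCF positions and the
`chrom_pos_ref_alt` variant key are 1-based; an SNV at position p
occupies [p−1, p). Point-in-interval tests are therefore left-closed,
right-open, delegated to `GenomicRanges::findOverlaps` and
cross-checked in the tests against a brute-force O(n·m) scan.

## Panels, structural variants, reports

Panel screening uppercases symbols and matches exactly (an optional
alias map hook accepts HGNC alias files); a multi-gene annotation such
as `RAD51D,RAD51L3-RFFL` tests each symbol independently, producing one
hit per matching symbol but counting once toward the variant total.
Structural variants are retained when they passed the caller's filters,
are carried by every case, do not overlap a common (gnomAD AF > 1%)
structural variant — strictly greater, so AF = 1% survives — and overlap
at least one panel gene's transcript bounds (gene-level, not
exon-resolved, matching the published gene-level criterion).

Reports tier every retained variant exactly once: tier 1 = panel hit,
tier 2 = retained coding without a panel hit, tier 3 = retained
non-coding without a panel hit; totals are conserved by construction.
`exportPathwayInput()` emits the distinct gene symbols of retained
segregating coding candidates with CADD > 20 — the documented input of
the downstream (proprietary) pathway analysis, which itself is out of
scope. The package deliberately makes no per-family single-gene call:
the final candidate selection in such studies is literature- and
validation-driven, a manual step.

## The synthetic cohort generator

`simulateCohort()` emulates the cohort structure of the motivating
study: three families (templates `trio`, `extended_9`,
`three_generation`; 7 affected and 10 unaffected members in total), one
planted dominant causal variant per family, and annotated background
variants. The defaults are the package's declared study conditions:

| quantity | default | note |
|---|---|---|
| background variants | 500 | joint call set, one chromosome |
| MAF | 0.3 point mass at 0 + 0.7 Beta(0.5, 20)·0.05 | private + rare tail |
| CADD PHRED | Gamma(shape 2, scale 4), truncated at 60 | mean 8 |
| conservation | latent Gaussian shared with CADD, ρ = 0.6 | GERP/PhastCons/PhyloP are transforms of one correlated latent |
| predictor calls | Bernoulli(logistic((CADD − 15)/4)) | deleteriousness tracks CADD |
| per-sample depth | Poisson(30) | strand counts Binomial-split |
| penetrance / phenocopy | 1 / 0 | exact segregation |

These distributions are explicit conventions (the motivating study
publishes none); they were chosen once to give realistic funnel
attrition (~1–5% of background variants survive the coding cascade) at
desk scale, and they are not tuned further. Founder genotypes are drawn
from Hardy–Weinberg at the sampled MAF and transmitted Mendelianly;
private (MAF 0) variants appear as a singleton heterozygote in one
random *founder*, so background genotypes are Mendelian-consistent by
construction. The planted variant is carried by every case and obligate
carrier and absent from controls; `phenocopyRate` is the probability an
affected case does *not* carry it, and `1 − penetrance` the probability
an unaffected control does. Penetrance-leaked carrier controls are
assigned independently of descent, so the Mendelian-consistency
guarantee is stated for background variants only. The seed fully
determines the output, down to byte-identical files.

What the simulator does **not** emulate: linkage disequilibrium,
population structure, sequence context (no reads, no mapping artifacts),
per-gene annotation realism, or the correlation structure of real
predictor panels. Passing the recovery benchmark therefore shows the
*pipeline logic* is sound — a variant with the planted profile cannot be
lost, and degradations behave monotonically — not that the thresholds
are optimal for any real cohort.

## Reconstructed study fixtures

The bundled fixtures reconstruct the published summary tables of the
motivating three-family study: 36 missense and 9 nonsense candidates
with their CADD/intolerance/vote columns, the 11 variants matching a
565-gene cancer-predisposition panel (9 genes) and the 25 variants
matching a 2,383-gene familial-HL candidate list (23 genes), the three
pedigrees, and the per-family UTR counts. Printed vote counts are
expanded deterministically (the first k predictors vote positive); only
the matched panel *subsets* are redistributed, not the full panels. Two
published inconsistencies are surfaced rather than resolved: the text
says 37 missense candidates where the table prints 36 rows (36 + 9
matches the study's own total of 45), and the stated 5'UTR total of 523
differs from the sum of its printed per-family parts (449); the fixtures
follow the printed tables and per-family figures. The prose also names
NCOA1 where the table prints NCOA2; the fixture follows the table.
Family 3's carrier founder is not identified in the source; the fixture
marks I-1 as the obligate carrier, a convention. The relative with
uterine cancer in family 2 is a control by default, as sequenced; the
PED role column can override this.

## Problem sizes and numerical choices

The test suite and acceptance script run at desk scale by design:
exhaustive segregation checks enumerate all dosage assignments
(including missing) on five pedigree shapes of up to four members;
interval intersection is fuzzed on 1,000 variant/interval pairs against
the brute-force scan; the recovery benchmark uses 20 replicates × 3
families of 500 background variants. Numeric output is serialized with
15 significant digits, which round-trips every annotation value the
package writes; simulated MAFs are rounded to 6 significant digits
before writing for the same reason. Ties in every ranking are broken by
(chrom, pos) with chromosomes ordered 1–22, X, Y, MT.

## Limitations

Only the dominant model is implemented (no recessive/compound-het, no de
novo detection, no kinship verification). Variant calling, annotation
and score computation are upstream: the package consumes scores, it
never recomputes them. Non-coding interpretation is limited to the
UTR/flank windows and the supplied tracks; intronic and intergenic
variants pass through the funnel but are never prioritized, matching
the scope of the motivating analysis.
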