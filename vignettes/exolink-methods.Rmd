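---
title: "Methods: family-based exome prioritization and two-point parametric linkage"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: family-based exome prioritization and two-point parametric linkage}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(exolink)
```

## The problem

A multiplex family segregating an apparently dominant trait — here
modeled on a large primary open-angle glaucoma (POAG) kindred with
eight affected siblings, one unaffected sibling, and deceased,
untyped parents — is exome-sequenced in a subset of affected members.
The analytic task has two halves:

1. **Prioritization**: reduce tens of thousands of coding variants to
   a handful of candidates by requiring sharing among affected
   individuals, rarity, a damaging consequence class, and a
   deleteriousness/conservation score, then confirm co-segregation in
   the rest of the family and absence from population-matched
   controls.
2. **Linkage**: quantify the evidence that the candidate region
   co-segregates with disease via a parametric LOD score, and compare
   it with the maximum the pedigree structure can support.

`exolink` implements both halves plus a seeded simulator that
generates complete synthetic studies, so that the whole pipeline can
be validated end-to-end against planted truth.

## The filtering cascade

`run_cascade()` applies, in order:

| stage | rule | default |
|---|---|---|
| sharing | every affected sample carries ≥ 1 alternate allele | — |
| population frequency | exclude if max AF across sources > `af_max` | 0.005 |
| in-house frequency | exclude if in-house fraction > `inhouse_max` | 0.005 |
| region | keep exonic and canonical splice-site records | — |
| consequence | drop synonymous substitutions | — |
| score rule | keep if Grantham > 80 **or** phyloP > 2.7 | strict |

Decisions worth making explicit:

* **All thresholds are strict** (`>` excludes, `>` includes for the
  score arms), following the usual "frequency > 0.5%", "Grantham
  > 80", "phyloP > 2.7" phrasing of such protocols. A variant with AF
  exactly 0.005 is kept; a variant with Grantham exactly 80 and phyloP
  exactly 2.7 is dropped.
* **The two score filters are parallel, not sequential**, and the
  candidate set is their union. Per-stage tables in the literature
  sometimes print the two counts stacked as if sequential, which
  cannot produce a final candidate set larger than the smaller count;
  per-sample counts are therefore reported for both arms
  independently, and the survivor list is
  `{Grantham > 80} ∪ {phyloP > 2.7}`.
* **Absence is not zero.** A variant with no frequency annotation in
  any source is novel and is retained; a missing phyloP fails only the
  phyloP arm; a nonsynonymous record without a parseable protein
  change raises a warning and fails only the Grantham arm.
* A missing genotype in an affected sample excludes the record at the
  sharing stage: sharing cannot be established from a no-call.
* Frequency sources are pluggable named columns (`AF_DBSNP`,
  `AF_EVS`, `AF_G1K` by default); filtering uses the maximum across
  the selected sources, i.e. presence above threshold in *any*
  database excludes.

cDNA-change strings are treated as opaque labels throughout (strand
and transcript conventions differ across sources); all scoring parses
the protein-change notation instead.

## Grantham distances

The Grantham distance combines side-chain composition, polarity and
molecular volume:

$$D(a,b) = \rho\left[\alpha(c_a-c_b)^2 + \beta(p_a-p_b)^2 +
\gamma(v_a-v_b)^2\right]^{1/2}$$

with $\alpha = 1.833$, $\beta = 0.1018$, $\gamma = 0.000399$ and
$\rho = 50.723$ scaling the mean of the 190 unordered residue-pair
distances to 100.

The canonical published integer matrix is **not** a pure function of
this formula: recomputing from the property table and rounding
reproduces it only to within ±1 for a handful of pairs (and Asp–Trp,
printed 181 against a recomputed 190.6, further off), an artifact of
how the original table was produced. Because the published integers
are what annotation pipelines and the surrounding literature quote,
`grantham_distance()` defaults to the embedded published matrix and
exposes the recomputation as `method = "formula"`.
`grantham_selfcheck()` — run at package load — verifies symmetry, the
zero diagonal, and published/formula agreement within one unit outside
the documented Asp–Trp exception.

## Segregation and the control screen

`segregates_dominant()` requires every typed affected member to carry
the variant; `strict_unaffected = TRUE` (default) additionally
requires every typed unaffected member to be homozygous reference.
The strict default matches the fully co-segregating pattern expected
of a causal variant in a strongly loaded family; the tolerant mode
exists because a 95%-penetrance model itself predicts occasional
unaffected carriers, which are then counted rather than fatal. Untyped
members (the deceased parents) are ignored by the check but retained
in the pedigree — the likelihood machinery needs them.

The recessive scan (`recessive_candidates()`) reports genes in which
all typed affected members are homozygous for one variant or carry two
or more distinct heterozygous variants. With both parents unavailable,
candidate pairs cannot be phased by transmission, so compound-het
candidates are flagged `phased = FALSE` rather than resolved.

`control_screen()` returns carrier counts against a cohort (default
retention cut: 0 carriers). A variant absent from the cohort table
counts as 0 with a logged note — an unobserved variant is not evidence
of carriers.

## Two-locus pedigree likelihood

The disease locus is biallelic with allele frequency $q$ and
penetrances $(f_{DD}, f_{Dd}, f_{dd})$; the default model is the rare
dominant configuration $q = 10^{-4}$, $f_{DD} = f_{Dd} = 0.95$,
$f_{dd} = 0$ (no phenocopies; the penetrance triple is fully
configurable). A marker with $k$ alleles is linked at recombination
fraction $\theta$. States are *ordered* haplotype pairs: haplotype =
(disease allele, marker allele), $(2k)^2$ genotype states per
individual.

* **Founder priors**: product of allele frequencies (linkage
  equilibrium).
* **Transmission**: each parental haplotype passes intact with
  probability $(1-\theta)/2$; the two recombinant disease–marker
  combinations get $\theta/2$ each.
* **Evidence**: affected members contribute their genotype's
  penetrance, unaffected the complement, unknown 1; typed members
  constrain the marker part to the observed unordered pair, untyped
  members are summed over.

`two_locus_likelihood()` evaluates the sum by Elston–Stewart-style
peeling, implemented as variable elimination over per-individual
genotype supports with a greedy smallest-join ordering; for loop-free
pedigrees this reduces to the classical nuclear-family peeling and is
exact. Numerical choices: factors are rescaled by their maximum after
every elimination with the log accumulated (no underflow at $q =
10^{-12}$), an impossible configuration yields a $-\infty$
log-likelihood sentinel rather than an error, and pedigrees with
marriage loops are refused up front (`is_loop_free()`), directing the
user to the enumeration engine. `brute_force_likelihood()` computes
the same sum by exhaustive enumeration over marker-consistent states —
exponential, guarded at $10^7$ configurations — and serves as the
independent oracle: peeling and enumeration agree to $<10^{-9}$ in
log-likelihood over randomized pedigrees in the test suite.

`lod_curve()` reports $\mathrm{LOD}(\theta) = \log_{10} L(\theta) -
\log_{10} L(0.5)$ on a grid (default 0 to 0.5 in steps of 0.01). The
value at $\theta = 0.5$ is exactly 0 by construction, and ties for the
maximum resolve toward smaller $\theta$.

### The structural ceiling

`max_pedigree_lod()` answers "what is the largest two-point LOD this
pedigree could ever yield?" by building a fully informative synthetic
marker — two globally unique equifrequent alleles per founder — whose
genotypes co-segregate perfectly with affection under a dominant
single-founder origin, and evaluating its LOD curve. For the shipped
`example_family()` (untyped parents, eight affected and one unaffected
typed sibs) under the default model the ceiling is **≈ 2.089 at
θ = 0**, frozen as a regression constant in the test suite. Two
analytic limits anchor the construction: a founder-only pedigree gives
0, and with full penetrance and a typed affected carrier parent the
ceiling equals the phase-unknown sibship closed form
$(n-1)\log_{10} 2$ (2.408 for nine children).

Suggestive scores approaching 2.5 that have been reported for
similarly sized kindreds imply more informative meioses than this
nine-sib approximation provides (for example partially reconstructable
parental genotypes or additional sibships); since the exact structure
and marker data of such families are generally not published, the
package documents its own example's ceiling rather than attempting to
reproduce any particular reported value. Multipoint (many-marker)
linkage in the Lander–Green sense is out of scope; the fully
informative single marker is the two-point proxy for it, and in fact
attains the same structural maximum.

### Sibship haplotype sharing

`sibship_shared_haplotype()` reconstructs, for a single sibship with
untyped parents, the parental haplotype assignments consistent with
Mendelian transmission at each marker (enumerating over alleles
observed in the sibship, with within-parent haplotype order
canonicalized) and reports the markers at which one parental
haplotype can be carried by all affected and avoided by all unaffected
siblings. Because the affected/unaffected partition pins down the
transmission pattern, per-marker support is automatically consistent
across markers, and the "shared segment" is the set of supporting
markers. Ambiguity is preserved: all consistent configurations are
returned (two siblings and one informative marker yield several), and
a marker with *no* consistent configuration raises an error — in
practice a genotyping-error signal. Recombination within the tested
marker set is not modeled; a marker separated from the disease locus
by a detectable crossover simply drops out of the shared set.

## The synthetic-data generator

`simulate_study()` emulates the statistical structure of a family
exome study, not its sequencing artifacts:

* **Pedigree**: `example_family()` — two untyped founders with
  unknown affection and nine typed offspring (eight affected, one
  unaffected). The true attachment of such a sibship to earlier
  generations is rarely recoverable from published material, so this
  single-sibship shape is a documented approximation.
* **Causal variant**: gene-dropped on one founder haplotype together
  with four linked microsatellite-style markers (six equifrequent
  alleles each, heterozygosity 5/6; recombination 0 by default —
  markers inside the disease haplotype block). By default the drop is
  rejection-sampled until the simulated affections reproduce the
  pedigree's observed pattern, i.e. genotypes are drawn conditional on
  phenotypes. Its annotations mirror a novel, conserved missense
  change (`p.Val37Met`, Grantham 21, phyloP 4.135, absent everywhere).
* **Background**: 200 variants by default, each Mendelianly dropped
  through the family at its own allele frequency, drawn from a
  two-component spectrum — 70% common, AF ~ U(0.01, 0.5); 30% rare,
  AF ~ U(0, 0.005), half of the rare ones novel — chosen to exercise
  both sides of every frequency filter. Background phyloP is
  U(−2, 7) and consequence classes span all seven categories, so both
  score arms and all region filters see traffic. About 5% of
  background records get an elevated in-house frequency to exercise
  that stage independently.
* **Controls**: 180 individuals; background carrier counts are
  binomial at the true AF, the causal variant has zero carriers.

One pseudo-random stream drives everything; a fixed seed makes all
four output files byte-identical across runs.

What the generator does **not** emulate — and what passing tests
therefore do not establish about real data: linkage disequilibrium
beyond the single causal haplotype block (background variants are
independent), genotyping and sequencing error, population structure in
the control cohort, allele-frequency estimation error in the
databases, and locus or allelic heterogeneity. The pipeline's recovery
rates on simulated studies are best read as correctness checks of the
filtering logic, not as power estimates for real exomes.

## Validation experiments shipped with the package

The test suite runs, among others: the nine canonical Grantham
regression scores and the 4-by-Grantham / 9-by-phyloP candidate
counts; peeling-versus-enumeration agreement (50 random pedigrees of
up to 8 members and 4 marker alleles, four θ values, tolerance
$10^{-9}$); the $(n-1)\log_{10}2$ sibship closed form (computed at
$q = 10^{-12}$, where the affected father is a heterozygous carrier
with probability 1 and the identity becomes exact to the stated
$10^{-9}$); θ recovery on 100 affection-conditioned gene drops of the
example family (θ̂ = 0 in every replicate at true θ = 0 on a 0.05
grid; mean θ̂ within [0.1, 0.3] at true θ = 0.2 — simulation at full
penetrance so the affection pattern identifies carriers, analysis
under the default 95%-penetrance model); and full-pipeline recovery of
the planted causal variant in 20 consecutive seeds at full penetrance.
Problem sizes (50 oracle instances, 100 replicates, 20 seeds, 200
background variants) are the package's chosen validation scale:
large enough to exercise every code path and expose systematic
errors, small enough to run routinely.

## Known limitations

* Two-point parametric linkage only — no multipoint HMM, no
  non-parametric (allele-sharing) scores.
* Loop-free pedigrees only; consanguinity requires loop-breaking,
  which is out of scope (the enumeration engine handles tiny looped
  cases).
* Autosomal inheritance only; no X-linked/hemizygous handling.
* Compound-heterozygous candidates are reported unphased.
* The VCF reader expects pre-split biallelic records and annotations
  in INFO keys; it is a consumer of annotation, never a predictor
  (consequence classes, phyloP, and functional predictions are inputs).
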