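---
title: "Soil nematode community analysis: indices, footprints, and ecosystem multifunctionality"
author: "nemafun"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Soil nematode community analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nemafun)
```

## The problem

Soil nematodes occupy every consumer level of the soil food web —
bacterivores (BF), fungivores (FF), plant parasites (PP), and
omnivores/predators (OP) — and their community structure integrates
disturbance history, decomposition pathways, and nutrient status. Each
genus also carries a colonizer–persister (c-p) score from 1
(fast-reproducing, disturbance-tolerant) to 5 (slow, sensitive), which
lets abundance data be read as a functional signal rather than a species
list. `nemafun` implements the full analysis chain used in grassland
disturbance studies of this kind: per-sample ecological indices,
trophic-group metabolic footprints and the faunal profile, a min–max
averaged ecosystem-multifunctionality (EMF) score for soil C/N/P
indicators, and the supporting community statistics. A seeded synthetic
generator reproduces the structure of a four-treatment, four-replicate
field design so the whole pipeline is testable without field data.

The central container is `NemaExperiment`, a `SummarizedExperiment` with
a genus × sample `abundance` assay (individuals per 100 g dry soil),
per-sample treatment labels in `colData`, and the per-genus trait
registry (trophic group, c-p value, per-individual fresh-weight biomass
in µg) in `rowData` once `attachTraits()` has been called. Soil
indicators live in `SoilIndicators`, an indicator × sample
`SummarizedExperiment` whose `category` column assigns each indicator to
C, N, P, or `driver` (soil water content and pH, which never enter EMF).

## Indices

For a sample with genus abundances $x_i$, total $N$, genus shares
$p_i$, and trophic-group shares $p'_g$:

* Shannon–Wiener $H' = -\sum p_i \ln p_i$ (natural logs throughout);
* Simpson dominance $\lambda = \sum p_i^2$;
* trophic diversity $TD = 1/\sum p'^2_g$;
* Margalef richness $SR = (S-1)/\ln N$ with $S$ the number of genera
  with positive abundance;
* maturity index $MI = \sum v_i f_i$, the c-p-weighted mean over the
  free-living (BF/FF/OP) sub-community;
* plant-parasite index $PPI = \sum v_i f'_i$ over the PP sub-community;
* channel ratio $NCR = BF/(BF+FF)$;
* Wasilewska index $WI = (BF+FF)/PP$.

Two definitions in this family are genuinely ambiguous in the field
literature and are resolved here as explicit design choices:

* **TD level.** $TD$ is computed over the four trophic-group shares of
  the sample total, the convention under which four equally abundant
  groups give $TD = 4$. A taxon-level alternative
  ($TD = 1/\sum p_i^2$, the reciprocal Simpson) is available via
  `tdLevel = "taxon"` in `diversityIndices()`/`indexTable()`.
* **MI denominator.** $f_i$ is the taxon share *within* the free-living
  sub-community (and $f'_i$ within the PP sub-community), so both
  indices are true weighted means bounded in $[1, 5]$; field values
  near 2–3 are only attainable under this normalisation.

Interpretation rules use strict inequalities: $NCR > 0.75$ labels the
decomposition pathway *bacterial* (otherwise *fungal-leaning*) and
$WI > 1$ labels the food web *good* (otherwise *poor*). Dominance
classes for relative abundances are strict as well: dominant $> 10\%$,
common $1$–$10\%$ (closed band: exactly 10% and exactly 1% are
*common*), rare $< 1\%$.

**Undefined-value policy.** $SR$ at $N \le 1$, $MI$/$PPI$ with an empty
sub-community, $NCR$ with $BF + FF = 0$, and $WI$ with $PP = 0$ are
carried as `NA`, listed in the `undefined` column of `indexTable()`,
reported once via `warning()`, and excluded from treatment means. They
are never coerced to zero, because 0 is a legal value of $NCR$ and of
several other indices.

```{r indices-example}
design <- fieldContrastDesign(seed = 1)
com <- generateCommunity(design)
head(indexTable(com)[, c("treatment", "shannon", "lambda", "mi", "ncr", "wi")], 4)
```

## Metabolic footprints and the faunal profile

The per-taxon metabolic footprint
$F_t = N_t\,(0.1\,W_t/m_t + 0.273\,W_t^{0.75})$ combines a production
term (lifetime biomass turnover scales inversely with the c-p value
$m_t$) and a respiration term (3/4-power metabolic scaling of body mass
$W_t$). Footprints are reported in the carbon-equivalent unit of the
supplied biomass; no unit conversion is attempted. `footprintTable()`
sums $F_t$ per trophic group (`bfmf`, `ffmf`, `ppmf`, `opmf`, total
`tnmf`), over the enrichment-indicator guilds (c-p 1 bacterivores +
c-p 2 fungivores → `fe`), and over the structure-indicator guilds
(c-p 3–5 bacterivores, fungivores, omnivores/predators → `fs`); the
functional footprint is $FMF = F_s F_e / 2$.

The faunal profile weights *abundances* rather than footprints, with
the standard faunal-analysis coefficients: enrichment component
$e = 3.2\,Ba_1 + 0.8\,Fu_2$, basal component
$b = 0.8\,(Ba_2 + Fu_2)$, structure component with weights 1.8 / 3.2 /
5.0 for c-p 3 / 4 / 5 guilds. Then $EI = 100\,e/(e+b)$ and
$SI = 100\,s/(s+b)$. Note that c-p 2 fungivores contribute to both $e$
and $b$ under this convention, so a community of cp-2 bacterivores and
fungivores has a small positive $EI$; only a pure cp-2 bacterivore
community sits at exactly $EI = 0$. All guild sets and weights live in
one configuration table (`faunalWeights()`, YAML-serialisable), so an
alternative convention — including excluding $Fu_2$ from $e$, or
admitting plant parasites, which are excluded by default — is a config
change, not a code change.

The faunal plot quadrants are not defined numerically in most published
figures; the package adopts the 50/50 convention: A ($EI \ge 50$,
$SI < 50$; enriched, unstructured), B (both $\ge 50$), C ($EI < 50$,
$SI \ge 50$), D (both $< 50$; degraded).

```{r faunal-example}
table(faunalProfile(com)$quadrant, treatments(com))
```

## Ecosystem multifunctionality

Each soil function indicator $j$ is min–max standardized across **all**
samples of the analysis, $f_{ij} = (x_{ij} - \min_j)/(\max_j - \min_j)$
— not per treatment, which would destroy cross-treatment comparability
of the resulting scores. A constant indicator maps to 0.5 everywhere
(with a warning) rather than being dropped, keeping the indicator count
stable; missing values are an error, never imputed. The single-function
scores EF-C, EF-N, EF-P are per-category means of $f_{ij}$ and EMF is
the unweighted mean over all indicators, so the identity
$N \cdot EMF = \sum_{cat} n_{cat}\,EF_{cat}$ holds to machine
precision and is asserted in the tests.

The field protocol this package is built around names fifteen
indicators but enumerates fourteen (5 carbon, 7 nitrogen, 2
phosphorus); the synthetic generator follows the enumeration. For real
data the category map is a user-supplied YAML/vector, so any indicator
list works unchanged.

## Community statistics

* `brayCurtis()` (vegan's `vegdist`) is the default community distance;
  `euclideanLog()` ($\log(x+1)$ Euclidean) is the alternative.
* `anosimTest()` / `mantelTest()` wrap vegan's seeded permutation tests;
  p-values use the add-one estimator $(1 + \#\{stat^* \ge stat\})/(n_{perm}+1)$
  and are therefore never exactly 0. `anosimStatistic()` exposes the
  rank-based $R$ for direct checking; the tests compare the permutation
  p against full enumeration on a 6-sample toy.
* `anovaLSD()` implements Fisher's LSD on the pooled ANOVA error mean
  square with an unadjusted pairwise t test per group pair, plus a
  compact letter display built from the maximal cliques of the
  "not significantly different" graph — sharing a letter is exactly
  equivalent to a pairwise $p > \alpha$.
* `vennPartition()` partitions the genus set by treatment-presence
  signature (presence = positive summed abundance within a treatment).
* `cooccurrenceNetwork()` connects genus pairs with
  $|\rho| \ge r_{min}$ (Spearman by default) and test $p \le p_{max}$
  (defaults 0.6 / 0.05), excludes zero-variance genera, and computes
  node/edge counts, average degree $2E/V$, positive/negative edge
  counts, and the modularity of igraph's deterministic greedy
  partition (weighted by $|\rho|$), so network metrics need no seed.
  Networks are built per treatment by default (`networksByTreatment()`);
  with four replicates per treatment they are illustrative — at
  $n = 4$ a Spearman test only reaches $p \le 0.05$ at $|\rho| = 1$ —
  which matches how such panels are used in field studies.

## The synthetic generator

`syntheticDesign()` describes the study conditions; its defaults are a
*null* version of the emulated field frame: 4 treatments (CK, NM, PM,
LM) × 4 replicates, 19 genera (the genus count shared by all
treatments in the emulated survey), expected total 1830 individuals per
100 g dry soil (the survey's mean density), lognormal rank-abundance
baseline (sdlog 1, the right-skewed genus-abundance shape typical of
soil fauna), and replicate noise `noiseCV = 0.15`, a realistic
between-core coefficient of variation for composite soil samples.
Treatment signal enters as multipliers: on the expected total, on
trophic-group and c-p-band composition (renormalised so the total
multiplier is honoured exactly in expectation), and on the bottom
tercile of the rank-abundance curve (thinning rare genera raises
dominance). Counts are rounded to integers for realism; every
downstream formula accepts reals, so rescaled densities work too.

`fieldContrastDesign()` is a named scenario encoding the emulated study's
contrast *directions*: PM raises the total by 37.74% with the
persister band rising slightly faster than the colonizer band (+39.37%
vs +36.54%); NM tilts composition toward bacterivores and
omnivores/predators and thins rare genera; LM raises the
plant-parasite share; soil drivers order the functions
CK > PM > NM > LM via moisture (highest in CK) and pH (highest in LM).
The recovery harness (`recoveryReport()`) always compares against the
multipliers *declared in the design*, so parameter-recovery tests are
not circular. Soil indicators are linear in their drivers — C
indicators decrease with pH, N/P indicators increase with soil water
content — with Gaussian residuals; the coefficients are arbitrary but
recorded in `metadata()$soil_model`, and only their signs mirror the
emulated system.

What the generator does **not** emulate: real genus identities and
trait values (unpublished for the emulated survey — fixtures carry
their own registry), spatial autocorrelation between mounds,
overdispersed count noise beyond the lognormal replicate factors, and
nonlinear soil–driver relationships. Passing tests therefore
demonstrate algorithmic correctness and statistical calibration under
realistic magnitudes, not field realism of any particular dataset.

```{r recovery-example}
rep <- recoveryReport(fieldContrastDesign(seed = 17, replicates = 30,
                                      noiseCV = 0.05))
round(rep$recovery_error["total", ], 2)
rep$emf_order
```

## Numerical choices

* Natural logarithms everywhere a formula prints $\ln$.
* Zero-abundance genera are excluded from $S$ and from all share sums.
* Strict boundaries as listed above (10% dominance, 0.75 NCR, 1 WI);
  quadrant boundaries are closed on the $\ge 50$ side.
* Sample totals of zero are an error in `relativeAbundance()` (a share
  is undefined), but empty *groups* are legal and yield zero rows in
  `aggregateAbundance()`.
* `anovaLSD()` refuses an error mean square of zero (all groups
  internally constant) rather than emitting letters from a degenerate
  fit.
* All stochastic entry points (`anosimTest`, `mantelTest`, the
  generators, `runPipeline`) take an explicit integer seed; generator
  streams are offsets of the design seed so traits, community, and soil
  draws are independent yet jointly reproducible.

## Problem sizes in the shipped tests

The test suite cross-checks every index, footprint, and profile value
against independent direct-summation oracles on 100 seeded random
communities of 4–30 genera; ANOSIM calibration uses a 6-sample/2-group
toy small enough for full enumeration (20 labelings) against 9,999
seeded permutations; effect recovery uses 200 replicates per arm at
multipliers 1.1 and 1.4 with `noiseCV = 0.05`, and type-I calibration
200 null designs at the field frame (4 × 4). These sizes were chosen to
make Monte-Carlo error a small fraction of each tolerance while keeping
the default suite around a minute.

## Known limitations

* Biomass values are user-supplied inputs; the package does not bundle
  a genus→biomass lookup.
* The structural-equation and random-forest analyses that often follow
  this pipeline are out of scope; `footprintTable()` +
  `functionScores()` export exactly the variable table such models
  consume.
* PCA/RDA ordinations are routine `stats`/vegan one-liners on the
  package's matrices and are intentionally not wrapped.
* The faunal quadrant convention and the EI/SI weight table are
  conventions, not identities; both are configurable and should be
  reported with results.
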