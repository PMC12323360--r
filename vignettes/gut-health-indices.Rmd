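---
title: "Gut health indices: models, parameters, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Gut health indices: models, parameters, and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gutindices)
```

## The two indices

`gutindices` scores stool metagenomic profiles with two complementary
dysbiosis markers.

**MAPI** (metagenomic aerotolerant predominance index) summarizes the
oxygen balance of a community. With $A$ the summed abundance of
aerotolerant genera and $S$ the summed abundance of strict anaerobic
genera in one sample,

$$\mathrm{MAPI} = \ln\!\left(\frac{A}{S}\right).$$

A score above 0 indicates predominance of aerotolerant organisms; healthy
adult gut communities sit far below 0, because strict anaerobes dominate
the colonic lumen. Which taxa count toward $A$ and $S$ is decided by a
curated aerotolerance table, not by code: the bundled starter table covers
common gut genera (Enterobacteriaceae genera, *Lactobacillus*,
*Streptococcus*, *Enterococcus* and similar facultative organisms as
aerotolerant; *Bacteroides*, *Faecalibacterium*, *Roseburia*,
*Akkermansia*, *Methanobrevibacter* and other obligate anaerobes on the
other side) and can be swapped for any curated list with the same TSV
schema. Whether a facultative anaerobe or microaerophile belongs on the
aerotolerant side is a curation decision; the table records it per taxon
in its citation column rather than resolving it globally. *Bifidobacterium*
is deliberately absent from the genus map — its strict anaerobes are
declared at species level through the override mechanism, which the
package honors for every genus, not only this one: one general rule is
safer than a special case.

**The keystone score** tracks a small panel of strictly anaerobic
commensals regarded as ecosystem engineers. For species $j$ with relative
proportion $p_{ij}$ in sample $i$,

$$L_{ij} = \log_{10}(p_{ij} + \epsilon), \qquad
  z_{ij} = \frac{L_{ij} - \bar L_{\cdot j}}{\mathrm{sd}(L_{\cdot j})}, \qquad
  K_i = \sum_j z_{ij},$$

with the default panel of six species: *Akkermansia muciniphila*,
*Bifidobacterium longum*, *Christensenella minuta*, *Faecalibacterium
prausnitzii*, *Methanobrevibacter smithii*, *Ruminococcus bromii*.
*M. smithii* is a panel member like the others; its anomalous direction
across phenotypes in real cohorts is a property of the data, not a scoring
rule. An eight-species variant exists in the keystone literature, and
*Blautia* spp. have been suggested as an addition; neither is bundled by
default, but a panel file (one binomial per line) replaces the default at
any call site.

## Assumptions and conventions

- **Z-score reference.** Z-scores are referenced to the *whole analyzed
  cohort*, all phenotypes pooled. Phenotype contrasts of $K$ only make
  sense on a common scale, which requires a pooled reference; a
  within-phenotype reference would remove the very differences being
  tested. A consequence worth remembering: keystone scores are
  cohort-relative and not comparable across separately scored cohorts.
- **Dispersion.** Sample standard deviation ($n-1$) throughout, the
  convention for cohort statistics. A species with zero SD across the
  cohort gets all-zero z-scores rather than NaNs.
- **Scale.** MAPI is scale-invariant (counts and proportions agree
  exactly), so no normalization is forced before scoring. Keystone scoring
  converts to relative proportions internally.
- **Phenotype binning.** Self-reported conditions map to three bins:
  empty list → healthy; bloating, constipation, gassiness or IBS → mild;
  celiac disease, Crohn's disease, gastroesophageal reflux disease,
  inflammatory bowel disease or ulcerative colitis → diseased. Diseased
  dominates mixed reports (a subject reporting both Crohn's disease and
  gassiness is diseased): each subject lands in exactly one bin and
  comorbid disease plausibly defines it. Reports containing only
  unrecognized free text are `unknown` — a distinct value, excluded from
  comparisons, rather than being forced into mild and contaminating the
  healthy/mild contrast. A bundled synonym map absorbs common survey
  spellings ("GERD", "IBD", "irritable bowel syndrome").

## Tunable parameters

| parameter | default | units/scale | why |
|---|---|---|---|
| MAPI pseudocount | 1e-6 | relative abundance | added to *both* sums, and only when one of them is zero: typical samples are untouched and the balanced-sample identity MAPI = 0 survives. The `pseudocount_used` flag is surfaced in every output so edge samples are auditable; whether to exclude such samples instead is left to the analyst. |
| keystone pseudocount $\epsilon$ | 1e-6 | relative abundance | floor for $\log_{10}$ of absences; a fixed floor keeps z-scores comparable across cohorts of different sequencing depth. |
| rank-sum mode | auto | — | exact enumeration when combined $n \le 12$ with no ties, else normal approximation with midranks, tie-corrected variance and continuity correction. Forcing `exact` is valid under ties too (enumeration over midranks). |
| FDR | Benjamini–Hochberg | — | the plain FDR step-up, no dependency correction. |

Two-sided alternatives are used throughout; no directional hypotheses are
baked in. For unpaired two-group contrasts (including cross-sectional
gender comparisons) the unpaired rank-sum test is the only defensible
choice — a signed-rank test would require pairing that does not exist.

## The synthetic cohort generator

Cohort-scale survey data with linked microbiome profiles are proprietary,
so the package ships a generator that emulates the statistical structure
the analysis pipeline assumes, making every stage testable end to end.

**Construction.** Each sample draws an age bin and gender from configured
frequencies, then a target score
$m \sim \mathcal N(\mu_{\text{phenotype}} + \delta_{\text{age bin}},\ \sigma)$.
The profile is built by inverting the MAPI formula: the aerotolerant
genera jointly receive the logistic fraction $1/(1+e^{-m})$ of the unit
classified mass, strict anaerobes the rest, with within-category masses
spread by a symmetric Dirichlet (concentration 1, i.e. uniform on the
simplex). Keystone species abundances are then drawn log-normally (base
10) and taken *out of the strict-anaerobe mass budget*, so the
aerotolerant/anaerobe ratio — and hence the target MAPI — is preserved
exactly (keystone draws are capped at 80% of the anaerobe budget; with the
default parameters the cap essentially never binds). Finally a condition
list consistent with the phenotype is attached, so phenotype binning can
be exercised on generated metadata.

**Calibration defaults, chosen once.**

- Healthy MAPI mean −5.2, SD 1.8 (natural-log units): the anchor
  distribution for healthy adults.
- Mild +0.5 and diseased +1.0 shifts: invented effect sizes, picked so
  omnibus tests at cohort scale are clearly significant while the
  distributions overlap heavily — group-separable but not
  individual-classifiable, which is how these indices behave on real
  cohorts.
- Age effect +0.5 for bins 61–70, 71–80 and 81+ (MAPI increases with
  age); 0 below 61.
- Demographic frequencies default to the age/gender composition of the
  healthy public reference cohort that anchors the −5.2/1.8 calibration
  (which has no 81+ stratum and a substantial gender-not-stated
  fraction).
- Keystone $\log_{10}$ means between −3.0 and −1.5 per species
  (*F. prausnitzii* most abundant at −1.5, *M. smithii* rarest at −3.0),
  SD 0.5: plausible gut ranges; z-scores are location-free, so only the
  ordering and spread matter. The disease shift (0.25 log10 units,
  half in mild, zero for *M. smithii*) depresses keystone species in
  disease while reproducing the *M. smithii* exception.
- MAPI draws are normal: the reference healthy distribution is
  summarized by mean ± SD only, and a normal is the minimal assumption
  consistent with that summary.

A single seeded RNG stream with fixed draw order (phenotype blocks in
healthy → mild → diseased order; per block: age bins, ages, gender,
target scores, keystone masses, category weights, condition lists) makes
cohorts bit-reproducible; the caller's RNG state is saved and restored.

**What the generator does not emulate** — and therefore what passing
tests do *not* show about real data: sequencing and classification noise,
read-count discreteness, compositional artifacts beyond renormalization,
taxon-taxon correlation structure, longitudinal dependence, or the
long-tailed genus repertoire of real guts (the panel has ~25 taxa).
Green tests demonstrate that the scoring and comparison machinery is
correct under the generator's assumptions, not that the indices separate
real clinical phenotypes.

## Numerical choices and degenerate inputs

- Text tables are UTF-8, decimal point only; both `;` and `|` lineage
  separators are accepted in every dialect, since harmonization pipelines
  convert between them. Duplicate taxon rows (distinct OTUs, one lineage)
  are summed, never errored — 100% OTU tables legitimately repeat
  lineages.
- The MGnify taxonomy-summary fix "remove the `s` at the start of each
  OTU" is ambiguous as usually stated; the default reading strips the
  superkingdom artifact (`sk__` → `k__`) and is exposed as a configurable
  regex rather than a hard-coded guess. All four fixes are idempotent.
- Table orientation is an explicit parameter; `auto` detection (which
  margin carries rank-prefixed labels) exists but silent transposition is
  never performed — it is a classic corruption source.
- Unassigned ranks (`g__`) give an absent genus, which can never match a
  genus-level classification; a bare species epithet with no genus cannot
  form a binomial and is likewise unmatchable.
- All-zero profiles, empty cohorts, single-sample cohorts (SD undefined),
  conflicting classification rows, and panel species matching two
  distinct lineages each raise a typed error naming the offender;
  batch scoring isolates per-sample failures in an `error` column instead
  of aborting the cohort.
- Exact rank-sum p-values are defined as the probability, over all
  equally likely labelings, of a U at least as far from its null mean as
  observed — the definition that stays valid under midranks. BH
  adjustment is monotone and capped at 1 but (like any step-up
  adjustment) not idempotent in general.

## Problem sizes in the test suite

The property suites run at sizes chosen to make the statistical
assertions sharp but cheap: direction recovery uses 100 replicate cohorts
at 200 samples per phenotype (at the default +0.5/+1.0 shifts the
phenotype orderings and the omnibus rejection are each recovered in ≥95%
of replicates); null calibration uses 1,000 three-group null score tables
of 30 samples per group, where the empirical type-I error at
$\alpha = 0.05$ must land in [0.03, 0.07] (binomial tolerance); the
healthy calibration check generates one cohort of 2,415 profiles.
Exhaustive rank-sum validation enumerates every two-group split of three
8-element multisets, with and without ties, against a brute-force
labeling oracle.

## A worked run

```{r example, eval = FALSE}
cfg <- sim_config(n = c(healthy = 200, mild = 200, diseased = 200),
                  seed = 42)
cohort <- generate_cohort(cfg)
scores <- score_cohort(cohort)        # MAPI + keystone + metadata
group_summary(scores, "phenotype")    # n, mean, SD, quartiles per bin
compare_by_bins(scores, "phenotype", "omnibus")       # Kruskal-Wallis
compare_by_bins(scores, "age_bin", "pairwise_fdr")    # rank-sum + BH
```

The same flow, from the shell:

```sh
Rscript $(Rscript -e 'cat(system.file("exec","gutindices.R",package="gutindices"))') \
  run --seed 42 --by phenotype --scheme omnibus --out-dir run1
```

## Known limitations

- The bundled aerotolerance table is a starter covering common gut
  genera, not a complete curated list; MAPI values depend on the table
  used, and tables must be version-pinned for comparability.
- Keystone scores are cohort-referenced and not transferable across
  cohorts scored separately.
- No BIOM/HDF5 input, no retrieval from public repositories, no
  diversity indices or ordination, and no figure rendering — the package
  ends at score tables, test results and group summaries.
- A redox-oriented companion score exists in the MAPI literature but has
  no published formula, and is out of scope here.
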