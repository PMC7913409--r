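---
title: "Case-control variant cosegregation: methods and design notes"
author: "VariantCoseg"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Case-control variant cosegregation: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(VariantCoseg)
```

# The problem

Small pedigreed populations with a heritable disease — here the motivating
system is hypertrophic cardiomyopathy (HCM) in Sphynx cats — allow
candidate causal variants to be found without genome-wide association
machinery: sequence a handful of affected and unaffected animals, keep the
variants whose presence tracks disease status, and genotype the survivors
in a larger validation population. `VariantCoseg` implements that cascade
as tested, reusable code: cohort input, cosegregation filtering, ACMG-style
pathogenicity classification, exact allelic association with penetrance
and relative risk, and a Ki67 immunohistochemistry group comparison, plus
a synthetic-cohort generator that exercises every stage with known ground
truth.

# The cohort model

Genotypes live in a `CohortGenotypes` object, an S4 class extending
`SummarizedExperiment`: one `"GT"` assay of alt-allele dosages (0, 1, 2,
`NA` for missing) with variant annotations as `rowData` and the sample
manifest as `colData`. Phenotypes are defined echocardiographically: an
affected cat must have a left ventricular end diastolic wall thickness of
at least 0.6 cm, an unaffected one less than 0.4 cm; the container's
validity method enforces both when wall measurements are recorded.
Multiallelic VCF records are rejected rather than auto-split, which keeps
dosage semantics unambiguous and pushes normalisation upstream
(`bcftools norm -m-`). Phase is ignored (`/` and `|` are equivalent)
because every statistic uses dosage only, and missing genotypes are
excluded from both numerator and denominator of every frequency — a
conservative carrier-counting convention, never imputation.

# The filter cascade

The discovery rule retains a variant when

* it is present — carrier status, dosage $\ge 1$ — in at least 50% of the
  informative affected cats,
* it is present in at most 5% of the informative control cats, and
* its predicted impact is moderate or high (missense, frameshift, stop or
  start changes, in-frame insertions/deletions, splice-site variants).

With 13 discovery controls, 5% is less than one cat, so the control rule
effectively demands absence from every discovery control. The validation
rule keeps the per-cat criterion for affected animals (at least 50%
carriers) but switches to a per-allele criterion for controls (at most 5%
of control alleles), which is how the two stages are phrased in practice:
a screening cohort is counted by animal, a genotyped population by allele.
Threshold comparisons are inclusive or exclusive exactly as phrased —
"at least 50%" is $\ge$, "5% or less" is $\le$, "more than 5%" excludes
with $>$.

Between the two stages, candidates are screened against two gene panels:
an established-causative-gene panel (sarcomeric HCM genes such as
*MYBPC3*, *MYH7*, *TNNI3*) used as a negative check, and a user-supplied
cardiac-involvement panel used to prioritise. The original prioritisation
used a commercial pathway tool, so the cardiac panel here is deliberately
an input file, not a built-in list; when no panel is supplied the pipeline
carries all filtered variants forward.

# Pathogenicity classification

`classifyVariant()` applies the rules in a fixed order, and frequency
exclusion preempts everything:

1. observed in more than 5% of control population alleles →
   `excluded_frequency`;
2. truncating consequence (stop gain, frameshift, splice acceptor/donor,
   start loss, exon deletion) → `pathogenic_truncating`;
3. missense at a well conserved residue with a deleterious in-silico
   consensus → `significant_missense`;
4. otherwise `not_significant`.

"Well conserved" is operationalised as residue-identity fraction
$\ge 0.90$ across the non-gap rows of an orthologue protein alignment
(configurable); gap rows carry no residue evidence and leave the
denominator. The consensus requires at least 2 of 3 deleterious verdicts
from PolyPhen-2, SIFT and PROVEAN. The per-program cut-offs are not part
of the guideline text, so the defaults follow each program's published
conventions — PolyPhen $\ge 0.85$ ("probably damaging"), SIFT $\le 0.05$,
PROVEAN $\le -2.5$ — and are configurable through
`inSilicoThresholds()`. A missing score is a non-vote: it neither helps
nor hurts, and the absolute vote requirement still applies, which is the
conservative reading when a predictor fails to score a site.

# Association statistics

The allelic test is a two-sided Fisher exact test on the $2\times2$ table
of variant vs reference alleles in cases vs controls, written from first
principles: with all margins fixed, the p-value is the sum of
hypergeometric point probabilities over every table whose probability does
not exceed that of the observed table (the "minimum likelihood" two-sided
definition used by mainstream implementations, with a relative tolerance
of $10^{-7}$ for floating-point ties). Probabilities are computed through
a cached log-factorial table, so tables with several hundred alleles per
margin remain exact. Tables with an empty row or column return $p = 1$
and are flagged. The test suite checks the implementation against
exhaustive enumeration for every table with all margins $\le 12$
(agreement within $10^{-9}$) and against `stats::fisher.test` on random
tables.

Penetrance and relative risk have no standard-free definition at the
summary-count level, so the package uses the standard epidemiological
ones: penetrance is affected carriers over all carriers in the combined
genotyped population, and relative risk is the carrier-vs-non-carrier
risk ratio $\frac{a/(a+b)}{c/(c+d)}$ with an optional Haldane 0.5
correction for zero cells. These definitions are stated prominently
because published summary figures for such cohorts are often not
reproducible from printed counts under any standard formula; the
package reports what its formulas compute. No multiple-testing
correction is applied by default (candidate slates at this stage are
tiny); a Bonferroni divisor is available in `associateVariant()`.

# Ki67 quantification

The counting protocol photographs each myocardial slide and counts Ki67
stained nuclei in five predefined areas (the four borders and the center);
the five area counts are summed to a single per-cat value. Group means
(HCM vs control) are compared with the classical pooled-variance
two-sample Student t test — that is what the name denotes — with
$df = n_1 + n_2 - 2$ and the two-sided p evaluated through the
regularized incomplete beta function,
$p = I_{\,df/(df+t^2)}(df/2, 1/2)$. A Welch option exists but is off by
default. Zero pooled variance with equal means yields $t = 0, p = 1$;
with unequal means the comparison is degenerate and flagged rather than
given an arbitrary p. Whether the per-cat value should be a sum over one
slide or an average over repeated photographs is ambiguous in such
protocols; the sum-per-slide reading is implemented, and because the t
statistic is scale invariant the choice does not affect significance.

# The synthetic-data generator

`simulateCohort()` emulates the study design the pipeline targets, and
its defaults are the study conditions, not tuning knobs:

* discovery cohort of 14 affected Sphynx + 13 unaffected controls;
  validation cohort of 71 affected + 214 non-Sphynx controls;
* a planted causal missense variant (chrA3:92439157 G>C in an
  *ALMS1*-like gene) carried by exactly 27 heterozygous and 35 homozygous
  affected validation cats and 2 heterozygous controls — carrier
  identities are sampled without replacement (hypergeometric assignment)
  rather than drawn binomially, so the published contingency table
  (97, 45, 2, 426) is reproduced exactly by a default simulation;
* discovery-cohort causal genotypes are all-carrier (the per-animal
  discovery counts are not published, and all-carrier is the
  configuration the discovery filter presumes);
* Ki67 counts for 4 affected and 3 control cats, Poisson per area with
  means 10/5 and 1/5 so per-cat sums average 10 and 1.

Values the study does not pin down were chosen once as field-realistic
defaults: 50 background variants (a candidate slate of the order a
post-WGS screen pursues), impact mix 5% high / 45% moderate / 30% low /
20% modifier, background allele frequencies from a rare-skewed
Beta(0.5, 3) shared between groups (background variants are null and
independent across sites — the analysis uses no linkage structure), 1%
genotype missingness on background sites, and benign-mode in-silico score
mixtures under which a 2-of-3 deleterious consensus occurs in well under
2% of draws. The orthologue alignment is simulated with one column per
missense variant; the causal column is a fully conserved glycine, and one
distant orthologue row carries gaps to exercise gap exclusion.

Each artifact (manifest, genotypes, scores, alignment, Ki67 counts) draws
from its own random stream keyed on `(seed, artifact)`, so regenerating
one output never perturbs the others, and a repeated seed reproduces
every file byte for byte.

What the generator does **not** emulate: linkage disequilibrium,
relatedness/kinship structure (the analysis applies no kinship
correction), sequencing error, population stratification between Sphynx
and control breeds, and genuine biological score correlations between
predictors. Passing tests therefore demonstrate correctness of the
pipeline's logic under the stated sampling model, not robustness of the
study design to confounding in real cohorts.

# Numerical choices and degenerate inputs

* Fisher p-values are clipped to $[0, 1]$; the tie tolerance is relative
  ($10^{-7}$) so that equal-probability tables on either side are
  included regardless of scale.
* All-missing genotype groups raise errors ("no informative samples")
  instead of returning `NaN`.
* Conservation on an all-gap column is an error, not 0.
* An empty call set flows through the whole pipeline with zero counts and
  no error.
* Seeds are kept within 32-bit integer range; the simulator validates
  $|\mathrm{seed}| \le 2^{28}$ before deriving per-artifact streams.

# Problem sizes used by the test suite

The suite runs the full pipeline on 100 default cohorts (51 variants
$\times$ 312 samples each) for the planted-variant recovery check,
enumerates all $2\times2$ tables with margins $\le 12$ (about 8,000
tables) for the exact-test oracle, uses 1,000 replicates for each null
calibration, and 10,000 simulated cats for the Ki67 law-of-large-numbers
check. Parameter recovery uses 5,000 + 5,000 validation samples with a
reduced background slate. These sizes were chosen to give stable
Monte-Carlo estimates while keeping a complete test run in the
low minutes.

# Known limitations

* The manual steps of such studies — visual inspection of alignments for
  larger indels, pathway-tool prioritisation — have no algorithmic
  counterpart here; the cardiac panel is a user input and the inspection
  step is at most a report flag.
* Published summary statistics (penetrance, relative risk, rounded allele
  frequencies) may be irreproducible from printed counts; the package
  documents its formulas and reports what they compute.
* The pipeline performs no kinship or population-structure correction and
  no multiple-testing correction by default, mirroring the analysis it
  re-implements; both matter for cohorts larger or less pedigreed than
  this design.
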