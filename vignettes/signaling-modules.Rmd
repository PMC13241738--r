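---
title: "Discovering neurotransmitter signaling modules from regional proteomes"
author: "ProteoNT"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Discovering neurotransmitter signaling modules from regional proteomes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ProteoNT)
```

# The analysis

ProteoNT integrates two measurement layers acquired from the same brain
regions of a WT/transgenic × 4/7-month factorial design: label-free
quantitative proteomics (MS1 precursor intensities, three biological
replicates per group per region) and an eleven-analyte monoamine panel
quantified by HPLC with electrochemical detection (four replicates per
group per region). The question the pipeline answers is regional: in which
brain regions does a neurotransmitter-linked pathway — dopamine or
serotonin receptor signaling, or the corresponding degradation pathway —
change in a direction that *explains* the measured change in the
transmitter itself?

The chain is:

1. **Differential abundance.** Intensities are normalized so every sample
   column sums to the across-sample mean of the original totals (total
   peptide-amount normalization; within-sample ratios untouched), proteins
   identified by a single unique peptide are removed, and each protein is
   tested by an unpaired two-tailed *t* test on log2 intensities between
   the 4- and 7-month groups of one genotype. The signed ranking statistic
   sign(log2FC) × −log10(p) orders the proteome for enrichment.
2. **Pathway level.** Preranked gene-set enrichment scores each set by the
   weighted running-sum statistic, with gene-set permutation providing
   normalized enrichment scores, p-values and FDR q-values (tiers at
   q < 0.25 and q < 0.05). Separately, for sets whose members carry
   expected directions under activation, the activation z-score
   (n~consistent~ − n~inconsistent~)/√N, gated by a right-tailed Fisher
   over-representation p, classifies each pathway as activated, inhibited
   or not significant.
3. **Neurotransmitter level.** Per analyte, a two-way region × age ANOVA
   with interaction supplies a pooled error term; the seven simple-effect
   contrasts (7 mo − 4 mo within each region) are Sidak-adjusted as one
   family, and each (region, analyte) cell receives an up / down / flat /
   undetected call.
4. **Integration.** An analyte→module map with polarities (+1: analyte
   increase is concordant with activation; −1: the reverse) joins the two
   layers. A (region, module) pair is *selected* when the sign product
   matches and at least one declared key regulator of the module is itself
   significantly changed. Records that cannot be evaluated (flat or
   undetected analyte, non-significant module) are retained in the output
   for audit, never silently dropped.

# Statistical definitions and their provenance

The enrichment score walks the ranked list accumulating
|r|^w^/Σ|r|^w^ at in-set positions and −1/(N − N~hit~) elsewhere, and
reports the signed maximum absolute deviation (weight w = 1 by default,
the convention of the preranked tool family; w = 0 gives the classic
Kolmogorov–Smirnov statistic). Gene-set permutation is the only null
available to preranked input: null scores come from random same-size
member draws from the ranked universe, shared across sets of equal size
(the draws are exchangeable in size). NES divides the observed ES by the
mean absolute same-sign null ES; the permutation p-value is add-one
corrected within the same-sign stratum, so it is never zero and is
uniform under the null; the FDR q compares the pooled null NES
distribution with the observed NES distribution within each sign, with
step-up monotone enforcement.

The activation z-score is the published vendor definition used by
commercial pathway-analysis suites — the package documents it as an
external definition rather than a novel statistic. Which members count is
governed by `sigRule` (default raw p < 0.05): whether the original
analyses counted all mapped members or only significant ones is not
knowable from typical methods text, so the rule is exposed rather than
hard-coded.

The Sidak adjustment 1 − (1 − p)^m^ is applied over the *m* contrasts
actually tested; wholly censored cells reduce *m*. The family default —
the seven per-region age contrasts within one genotype — mirrors
per-region significance stars in regional neurochemistry figures; the
genotype × age factorization within one region is also supported because
published legends often leave the factorization ambiguous.

# Tunable parameters

| Parameter | Default | Why |
|---|---|---|
| `minUnique` (peptide filter) | 2 | high-confidence identification rule |
| `varianceMode` | `"welch"` | n = 3 per group, no evidence of equal variances; `"pooled"` is exact under homoscedastic noise |
| volcano cuts `pCut`, `fcCut` | 0.05, 0.58 | raw p and 1.5-fold, stated as assumptions — source analyses rarely print their volcano thresholds |
| GSEA `weight` | 1 | preranked tool default |
| `nPerm` | 1000 | q-value resolution of ~10^-3^ at desk-scale runtime |
| set-size filters | 3–500 | tool convention; prevents degenerate ES |
| z presets | strict (2.0, 1.3), comparative (0.5, 1.3) | primary pathway calls vs cross-region comparative profiles |
| `sigRule` | raw p < 0.05 | member-significance criterion, configurable to q |
| neurochem α | 0.05 | the conventional significance level |
| polarity map | receptor +1, degradation −1 (substrate), +1 (products) | minimal formalization of "consistent directional correlation"; fully overridable and echoed in output |
| key-regulator k | 1 | single validated regulators per module are the norm |

# What the generator emulates — and what it does not

`simConfig()` fixes the study conditions: seven regions (OB, Ctx, STR,
Hip, Tha, SN, CB), WT/TG × 4/7 months, three proteomic and four
neurochemical replicates per group. Abundance noise is log-normal
(Gaussian on log2, default sd 0.25, a replicate CV near 19% typical of
label-free MS1 data), matching the t-test assumptions of the analysis
stage. Planted pathway shifts move a stated fraction (default 80%) of a
module's members by a stated log2 effect (default 1) in the TG 7-month
group of designated regions, signed by each member's direction
annotation, so the disease-progression contrast recovers them. Analyte
effects are fold changes applied at 7 months with log-normal measurement
noise (CV 0.15) and left-censoring at per-analyte detection limits; an
analyte configured absent (serotonin, in the shipped scenario, matching
its reported non-detectability across regions) yields all-flagged records
everywhere. The eleven-analyte vocabulary and four curated directed
modules (dopamine/serotonin receptor signaling and degradation, with
Drd1–Drd5/Adcy, Maoa/Maob/Comt, Htr1a/Arrb1 and Aldh2 among members and
key regulators) are built in.

Unique-peptide counts are abundance-linked, with a configurable fraction
of low-abundance filler proteins assigned exactly one peptide to exercise
the identification filter. The curated module members are always assigned
at least two peptides: they emulate proteins the study design quantified
confidently, which keeps the planted truth recoverable by construction
rather than hostage to the peptide lottery.

The generator deliberately does **not** emulate: peptide-level
identification and FDR, intensity-dependent missingness (an optional
dropout mechanism exists but defaults off, since real missingness
handling is rarely reported), batch or run-order structure,
between-region abundance differences, or correlated noise across
proteins. Passing tests therefore demonstrate correctness of the
statistical machinery under a clean factorial model — not robustness to
the full messiness of instrument data.

# Numerical choices

* Zero intensities become half the smallest positive value in the matrix
  before log2 — avoids −∞ while preserving order.
* Constant data in both groups with equal means gives p = 1 (avoids 0/0
  in the t statistic); equal variances with different means floor p at
  10^-300^, the same floor applied before −log10 in the ranking statistic.
* Ranked-list ties break on protein accession (stable, so permutation
  tests are deterministic).
* ES sign on a tie: when the maximum positive and negative running-sum
  deviations agree within 10^-9^, the positive one is reported. A
  first-position rule would make the sign depend on floating-point
  summation order; this rule is order-independent and is used identically
  by the implementation, the O(k) permutation fast path and the
  brute-force oracle in the test suite.
* NES is undefined when all same-sign null scores are zero (tiny
  universes); such sets are reported not-significant rather than dividing
  by zero.
* Below-LOD values in partially censored cells are substituted by LOD/2,
  standard left-censoring practice; wholly censored cells are excluded
  from the ANOVA and propagate `undetected` → `not_evaluable`
  downstream.

# Design choices where the ground was open

* **Welch default, pooled for calibration.** With n = 3 and no variance
  information, Welch is the safer default; under the generator's
  homoscedastic noise it is measurably conservative (empirical type-I
  error near 0.03 at α = 0.05), so the pooled test — exact under those
  conditions — carries the calibration checks, and a companion check
  asserts Welch errs only on the conservative side.
* **BH everywhere at the protein level.** Protein-level multiplicity
  handling is typically unstated; BH is adopted uniformly, matching its
  use for ontology terms.
* **Replicate count for neurochemistry.** Published legends disagree
  (n = 3 vs n = 4); the generator defaults to 4, the experimental-design
  statement, and exposes the count.
* **Metabolites in the concordance map.** Whether acid metabolites
  (DOPAC, HVA, 3-MT, 5HIAA) entered the original concordance with their
  parent transmitter's modules is unstated; the default maps them to
  their producing degradation module with polarity +1, overridable via
  the map argument.
* **Per-region gene-set counts are not reproduced.** The exact collection
  subset and size filters behind reported "34–37 gene sets per region"
  are unrecoverable, so no test asserts them.

# Problem sizes used by the test suite

The suite's simulations are sized for desk-scale reruns: 2000-protein
universes for calibration and recovery checks, 1000 permutations for
enrichment, 2000 Monte-Carlo repetitions for the Sidak family-wise error
(the invariant is stated at 10,000; 2000 keeps the same conclusion with a
3-standard-error band), and exhaustive enumeration of all 16,354 set
placements on ranked lists up to length 12 for the enrichment-score
oracle. `scripts/acceptance.R` reruns all of these from one seed.

# Known limitations

* The activation z-score is brittle for small directed modules: with
  6–9 annotated members, a single chance-significant member voting
  against the annotation can pull z below the strict 2.0 cutoff, so
  end-to-end recovery of small planted modules is seed-dependent at that
  preset. Real pathway collections with dozens of annotated members are
  far less sensitive.
* Pathway topology, causal-network scoring and leading-edge analysis are
  out of scope; the activation call is overlap-plus-direction only.
* Censoring is handled by LOD/2 substitution, not by maximum-likelihood
  censored regression; heavily censored cells (beyond the wholly-censored
  exclusion) will bias effects toward zero.
* The mRNA–protein concordance assessment is qualitative (direction and
  significance only), by design.
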