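---
title: "Methods: cross-platform genotype concordance evaluation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: cross-platform genotype concordance evaluation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(genoconcord)
```

## The problem

When the same individuals are genotyped on two platforms — here a
sequence-based platform (direct next-generation sequencing, or imputation
to hard calls) and a SNP microarray — neither call set is a gold standard,
but their disagreement pattern is informative. Discordance among called
genotypes bounds the genotyping error rate from below (if the platforms
err independently, almost every error surfaces as a discordant pair;
correlated errors make the bound optimistic). Missingness quantifies
power loss directly. And discordance that varies with a phenotype is a
warning sign for differential genotyping error, which inflates type I
error in association tests, whereas phenotype-independent error "only"
costs power.

This vignette records how each statistic in `genoconcord` is defined, the
choices that were genuinely open and how we resolved them, what the
simulator does and does not emulate, and the package's known limits.

## Harmonization

Variants are matched across platforms **by rs identifier alone**.
Chromosome/position disagreement between platforms for a matched rs id is
a warning, not an exclusion: coordinates differ legitimately across
annotation builds, while the rs id is the intended join key. Samples
present on only one platform are dropped with a logged count.

Calls are coded per variant relative to that call set's own major/minor
alleles (AA = two major, AB = het, BB = two minor, XX = missing). Formats
that do not state major/minor (PLINK text, VCF) get a file-local
assignment: the more frequent allele among called genotypes is major,
ties broken alphabetically — deterministic and reproducible from the file
alone. A monomorphic variant gets a placeholder minor allele (first
nucleotide alphabetically not equal to the major) so the record stays
well-formed; its calls are all AA and its MAF is 0.

For each matched variant the two allele pairs are classified as
`identical`, `swapped` (major/minor designation reversed — expected near
MAF 0.5, where sampling noise flips which allele is more frequent),
`strand_flip`, `strand_flip_swapped`, `mismatch`, or
`ambiguous_palindromic`. Two policies matter:

* **Default: `allow_strand_flip = FALSE`.** Any relation beyond
  identical/swapped is treated as a mismatch and excluded. This is the
  conservative reading appropriate for QC: a site where the two platforms
  report different bases is evidence of a real calling problem until
  proven otherwise, and strand provenance is rarely trustworthy enough to
  prove otherwise automatically.
* **Opt-in strand rescue.** With flips allowed, complement-strand sites
  are re-oriented instead of excluded, but A/T and C/G (palindromic)
  pairs become `ambiguous_palindromic` — for them a strand flip is
  indistinguishable from a designation swap — and are excluded by default
  (`drop_palindromic = TRUE`). Setting `drop_palindromic = FALSE` keeps
  them under the identity orientation, which is only defensible when MAF
  is far from 0.5.

The `swapped` transform relabels AA↔BB in the second call set (AB and XX
are invariant); `strand_flip` complements the allele metadata and leaves
calls untouched. Exclusions carry per-site reasons and both platforms'
allele pairs, and the accounting identity
`matched = retained + excluded` is asserted on every run.

## Cross-classification and overall discordance

Every (variant, sample) pair lands in exactly one of 16 cells
(sequence call × microarray call over {AA, AB, BB, XX}); the grand total
is always n_SNPs × n_samples. Two overall discordance proportions are
reported:

* `called_only`: the six off-diagonal cells among called genotypes,
  divided by the **grand total of all 16 cells**;
* `including_missing`: those six cells plus every pair where exactly one
  platform is missing, same denominator.

Two conventions here were open. First, the denominator: we use the grand
total for both modes (rather than restricting the called-only proportion
to called pairs) because the two modes then share a scale and their
difference is exactly the one-sided-missingness mass. Second, XX–XX
pairs: counted as *concordant-missing*, not discordant — both platforms
agree nothing was called. Both conventions affect the third decimal at
realistic missingness levels; they are fixed here and stated so the
numbers are reproducible.

The published pooled table for the GAW18 dual-platform comparison is
bundled as `gaw18_crossclass()` (its genotypes are access-restricted; the
pooled counts are public). It is the desk-scale check that the
conventions above reproduce the published headline figures — 2.63%
discordance including missing, 0.23% among called genotypes — which the
test suite and `scripts/acceptance.R` recompute.

## Conditional concordance rates

Per SNP *s* and microarray category *j*, the conditional rate vector is
P(sequence = *i* | microarray = *j*) = count(*i*, *j*; *s*) / count(·,
*j*; *s*). A column with zero denominator is *invalid* — flagged and
excluded from averages, never an error, because at moderate sample sizes
low-MAF SNPs routinely have no observed minor homozygote. Valid columns
sum to 1 within 1e-12 (pure arithmetic; the tolerance only guards
accumulated floating error).

Across-SNP summaries are **unweighted** by default (each SNP is one
observation), matching the per-SNP framing of the differential tests; a
count-weighted (pooled) alternative is available via
`summarize_rates(weighted = TRUE)`. Whether to weight was an open choice;
equal weighting is the default because the downstream t-tests treat SNPs
as the units of analysis, and mixing a pooled estimator with per-SNP
tests would be incoherent.

Both the across-SNP **SD** and the **SE of the mean** are reported, with
explicit column names. With hundreds of thousands of SNPs the SE is
vanishingly small, so parenthetical dispersion values of order 0.03–0.1
on such data can only describe SNP-to-SNP spread; reporting both avoids
any ambiguity about which is meant.

### MAF stratification

MAF is computed from called genotypes of one platform (default:
microarray, the platform with near-complete calls) as
(n_AB + 2 n_BB) / (2 n_called) — the minor-allele count under the
harmonized designation, deliberately unfolded so a designation/frequency
disagreement is visible rather than silently folded. Default bin edges
0.05, 0.1, 0.2, 0.3, 0.4, 0.5 (half-open, last bin closed) reflect the
common-variant setting: dual-platform designs exclude rarer SNPs because
arrays do not assay them. SNPs below the first edge (e.g. monomorphic in
the chosen source) fall into the lowest bin; SNPs with no called source
genotypes are logged and left unbinned.

## Differential analysis

Phenotype strata are derived from raw repeated measures with strict
thresholds: hypertensive iff any observed exam has SBP > 140 mm Hg or
DBP > 90 mm Hg (a subject at exactly 140/90 at every exam is *not*
hypertensive); ever-smoker iff any observed wave self-identifies; no
observed measurement gives `unknown`, and unknowns are excluded from
comparisons.

Per 4×4 cell, the two groups' per-SNP conditional rates are compared with
a **two-sample Welch (unequal-variance) t-test**, two-sided. The test
family was an open choice; Welch is the default because nothing
guarantees equal variances between, say, 464 NGS and 495 imputed samples,
and Welch costs essentially nothing when variances happen to be equal.
For the technology comparison, where the same SNP contributes one rate
per group, a paired-by-SNP variant (`paired = TRUE`) is provided.
Complete-case per cell: a SNP lacking a valid denominator in either group
is dropped from that cell's test.

Degenerate cells are defined, not errors: fewer than 2 SNPs in either
group → NA statistics; both groups constant and equal → t = 0, p = 1 (no
evidence of difference); both constant and unequal → NA (the statistic is
undefined). p-values are floored at machine precision and additionally
formatted as `"< 2.2e-16"` below it. No multiplicity correction is
applied across the 16 cells — the cells are one family of descriptive
screens, and raw p-values are the convention in concordance reporting — a
Bonferroni column is emitted for convenience.

The tests treat SNPs as independent observations. Linkage disequilibrium
between SNPs and relatedness between samples (family designs) both
violate that; the p-values are calibrated only under the simulator's
independence assumptions and should be read as descriptive on structured
real data. This is a documented assumption, not corrected for.

## Dosage resolution

Minor-allele dosages are AA = 0, AB = 1, BB = 2. A discordant called pair
is resolved to the **arithmetic mean** of the two dosages — the 50-50
weighting that is optimal under independence of the two error mechanisms:
0.5 for major-homozygote/het pairs, 1.5 for het/minor-homozygote pairs.
Two cases required a decision:

* **Opposite homozygotes** (AA vs BB) resolve to 1.0 by the same mean
  rule; since only adjacent-class cases are canonical, these cells remain
  identifiable via the `resolved_discordant` provenance code and the
  cross-classification counts.
* **One-sided missingness** uses the available platform's dosage (code
  `one_missing`) rather than propagating missingness: discarding a called
  genotype because the other platform failed would throw away
  information. Only XX–XX pairs yield a missing dosage.

Resolution is symmetric in its arguments and closed over
{0, 0.5, 1, 1.5, 2}.

## The simulator

`simulate_paired_dataset()` draws, per SNP, a MAF q from the configured
spectrum, truth genotypes i.i.d. with Hardy–Weinberg probabilities
((1−q)², 2q(1−q), q²), and then lets each platform observe the same truth
through its own 3×3 row-stochastic confusion matrix followed by
independent missingness. Optional mechanisms: a MAF-dependent multiplier
on off-diagonal error mass (errors concentrate at low MAF), and
phenotype-differential sequence-error matrices keyed to the simulated
hypertension label. Phenotypes are generated so the derivation rules
round-trip exactly (every hypertensive sample has an exam exceeding a
threshold; every non-hypertensive sample never does).

Defaults are the dual-platform study conditions the package targets: 959
samples (464 NGS / 495 imputed), MAF ~ U(0.05, 0.5) (common variants
only), sequence missingness 0.024 vs microarray 2×10⁻⁴ (the order of the
observed platform margins), called-error mass of 0.1–0.3% per row
concentrated on adjacent classes (het ↔ minor homozygote above all,
matching the observed dominant discordance classes), hypertension
prevalence 0.35 and smoking prevalence 0.25 (plausible for an adult
family cohort). The default 1000 SNPs keeps simulated studies desk-scale;
tests use 25–400 SNPs and 30–500 samples per scenario, with 10⁵-pair
configurations (200 × 500) for parameter recovery.

All randomness flows from one master seed through a fixed
stream-splitting scheme (`split_seed()`: sub-seed *k* is the *k*-th
`sample.int` draw under the master seed), so each stage can be
regenerated independently and full runs are byte-identical under a fixed
seed.

What the simulator does **not** emulate — and therefore what passing
tests do not establish about real data: linkage disequilibrium, pedigree
structure and transmission, correlated errors between platforms (e.g.
context-specific miscalls hitting both technologies), batch or plate
effects, the imputation algorithm itself (imputed calls are modelled as
just another confusion matrix), and any non-SNP variation. Parameter
recovery shows the pipeline is correct under independence; it does not
show real platforms err independently.

## Numerical and verification notes

* Conditional-column normalization is checked to 1e-12; confusion-matrix
  rows must sum to 1 within 1e-12.
* Monte-Carlo checks use exact binomial standard errors derived from the
  configured simulator parameters and realized denominators (for an
  unweighted mean of per-SNP rates, Var = S⁻² Σₛ p(1−p)/nₛ), with a
  3-SE acceptance band. Empirical across-SNP SDs are biased low for
  skewed small-p binomial rates and are not used as MC bounds.
* The Welch null calibration (`welch_null_calibration()`) runs 1000
  nondifferential replicates of 30 SNPs × 100 samples with moderate
  (3–5%) error rates — enough per-SNP variance for the t-test to be
  non-degenerate — and records the AB|AB cell's rejection rate at
  α = 0.05.
* Report TSVs use fixed formatting (6 significant digits, scientific
  p-values) so reruns diff cleanly; determinism is tested by
  byte-comparison of full report bundles.
* Oracle checks: pooled counts and per-SNP rates are compared against an
  explicit-loop recount on 5×5 fixtures; dosage resolution against an
  exhaustive elementwise enumeration of all 16 call pairs.

## Limitations

Biallelic SNPs only (multiallelics and indels are excluded at read time,
with logged reasons); no liftover between genome builds (rs-id matching
assumes consistent annotation); no Mendelian-error screening (assumed
done upstream); no posterior-probability dosage weighting beyond 50-50;
t-tests ignore LD and relatedness as discussed above. The allele-mismatch
sites that harmonization excludes are reported, not investigated —
distinguishing strand bookkeeping from genuine tri-allelic calling errors
needs information (strand annotation, frequency priors) outside this
package's inputs.
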