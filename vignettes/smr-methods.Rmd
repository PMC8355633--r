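---
title: "Methods: summary-data Mendelian randomization across GWAS and eQTL panels"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: summary-data Mendelian randomization across GWAS and eQTL panels}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(smrlink)
```

## The model

Two studies measure, at the same SNPs, two different marginal regressions:
a GWAS reports the per-allele effect of SNP $j$ on a trait
($\hat\beta_{GWAS,j}$, $SE_{GWAS,j}$) and an eQTL study reports the
per-allele effect of SNP $j$ on the expression of a probe $k$
($\hat\beta_{eQTL,jk}$, $SE_{eQTL,jk}$). If the SNP affects the trait
*through* expression, the two effects are proportional,
$\beta_{GWAS} = b_{xy}\,\beta_{eQTL}$, and the Wald ratio
$\hat b_{xy} = \hat\beta_{GWAS}/\hat\beta_{eQTL}$ estimates the causal
effect of expression on the trait with the SNP as instrument.

With $Z = \hat\beta/SE$ in each study, the test statistic used here is

$$T \;=\; \frac{Z_{GWAS}^2\, Z_{eQTL}^2}{Z_{GWAS}^2 + Z_{eQTL}^2},$$

half the harmonic mean of the two squared Z scores, referred to
$\chi^2_1$. Algebraically $T \le \min(Z_{GWAS}^2, Z_{eQTL}^2)$: a pair is
never more significant than its weaker arm, which is what makes the
statistic a test of *mediated* association rather than of either marginal
one. When the instrument is strong ($|Z_{eQTL}|$ large), $T \to
Z_{GWAS}^2$ and the test is exactly $\chi^2_1$-calibrated; with weaker
instruments it is conservative. Both limits are exercised by the test
suite (`smr_type1_error()` at median $|Z_{eQTL}| \approx 22$ sits inside
[0.040, 0.060] at $\alpha = 0.05$ over 2000 replicates).

Assumptions inherited from the instrumental-variable reading: the SNP is
associated with expression (relevance), and affects the trait only
through expression (no horizontal pleiotropy). The statistic cannot
distinguish causality from linkage — a SNP in LD with two distinct
functional variants, one for expression and one for the trait, produces
the same signal. No heterogeneity test is applied to filter such cases;
calls should be read as *risk gene candidates*.

## Multiple testing

Each merged dataset is thresholded at $\alpha / n_{probes}$ where
$n_{probes}$ is the probe count of the **source expression panel**, not
the number of pairs actually tested. The panel is the family over which
discovery is claimed; the merged subset depends on the GWAS it happened
to be crossed with. With the four panel sizes 33,323 (blood), 28,522
(brain), 7,350 (CD4) and 5,829 (CD8) this gives thresholds of
$1.5\times10^{-6}$, $1.8\times10^{-6}$, $6.8\times10^{-6}$ and
$8.6\times10^{-6}$ at two significant figures. Passing `n_probes`
explicitly to `run_smr()` (e.g. the tested-pair count) switches the
convention.

## Harmonization

Studies disagree about which allele is the "effect" allele, so effects
are aligned before the ratio is formed. The eQTL effect allele is the
reference: $b_{xy}$ then reads as trait change per expression-increasing
allele dose. Matching is by rsID alone (build-agnostic; no liftover).
Per pair the GWAS alleles are compared directly, then swapped
(sign-flip), then strand-complemented and re-compared; irreconcilable
pairs are dropped and counted. Palindromic variants (A/T, C/G) cannot be
strand-resolved from labels, so the default `"strict"` policy drops
them; `"lenient"` keeps them resolved by label match alone, for sources
known to share strand conventions. Note that $T$ squares the Z scores,
so alignment only matters for the *sign* of $b_{xy}$, not for the test.

## Instrument selection

`run_smr()` defaults to testing **every** harmonized SNP–probe pair
(`mode = "all_pairs"`): several cis SNPs may then support the same gene,
and the gene-level report counts them. The conventional alternative —
one top cis-eQTL per probe, selected at $p \le 5\times10^{-8}$
(`mode = "top_per_probe"`) — is provided; ties are broken by larger
$|Z_{eQTL}|$, then lexicographic SNP id, making selection deterministic.

## Numerical choices

* **P-values in log space.** $T$ grows like $Z^2$, so upper-tail
  probabilities underflow double precision near $|Z| \approx 38$.
  `p_smr(t, log.p = TRUE)` is used internally; results carry both
  `p_smr` and `log10_p`, and significance is compared in log space.
* **P printed as zero.** Input rows with $p = 0$ (underflow in the
  source) or missing $p$ are not discarded: $p$ is recomputed from
  $|\beta/SE|$ under a normal reference and clamped to the smallest
  positive double. $\beta$ or $SE$ missing is fatal for the row.
* **Degenerate inputs.** $T(0,0) = 0$ by the limit convention (the
  formula's limit along any ray); $\hat b_{xy}$ is undefined at
  $\beta_{eQTL} = 0$ and errors rather than returning infinity; the
  delta-method SE degenerates to $SE_{GWAS}/|\beta_{eQTL}|$ at
  $\beta_{GWAS} = 0$.
* **Duplicate eQTL keys.** Conflicting duplicate `(snp, probe)` rows
  keep the smallest p-value (then largest $|Z|$, then file order) —
  deterministic and favouring the strongest signal.
* **Overlap rate.** Cross-dataset gene overlap defaults to
  `min_fraction` ($|A \cap B| / \min(|A|,|B|)$), the reading under which
  a near-subset overlaps at ~100%; Jaccard is selectable. The rate of an
  empty set is defined as 0 with a warning.

## What the generator emulates — and what it does not

`sim_config()` encodes a two-sample design: two disjoint cohorts share
per-SNP allele frequencies (uniform on `maf_range`, default 0.05–0.5)
but are independent draws. Haplotypes come from a first-order
autoregressive latent Gaussian thresholded at $\Phi^{-1}(maf)$, so
marginal frequencies are exact, dosages are Hardy–Weinberg, and LD
decays geometrically with adjacent-SNP correlation `ld_rho` (default
0.5, a realistic magnitude for neighbouring cis SNPs). Expression is
`b_zx * dosage[causal] + N(0,1)`; the trait is `b_xy *` (the genetic
component of expression) `+ N(0,1)`; both cohorts are reduced to
marginal least-squares summary statistics — the only data the method
ever sees.

Defaults are the reference conditions of the test suite: `m_snps = 50`,
`b_zx = 0.5` (a strong instrument at $n = 5000$: $|Z_{eQTL}|$ around
20), `b_xy = 0.3`, cohorts of 5000, one causal probe plus
`n_null_probes = 9` noise probes, an emulated panel of
`n_probes_total = 1000` for thresholding, and `flip_fraction = 0.3` of
SNPs reported on the opposite allele in the GWAS table to exercise
harmonization. Allele pairs are drawn from the non-palindromic
transitions/transversions so strict harmonization never drops simulated
variants.

Deliberately **not** modelled: realistic LD from reference panels,
case-control ascertainment (the trait is quantitative; the method
operates on $\beta/SE$ scale where the distinction is immaterial for
calibration), allele-frequency-dependent effect sizes, confounding of
expression and trait through environment, and trans-eQTLs. A passing
suite therefore demonstrates statistical correctness and calibration of
the machinery, not robustness to pleiotropy or LD contamination on real
data. The clean causal model also means the simulation cannot produce
the linkage false-positives discussed above; `b_xy = 0` with the causal
model is a sharp null.

## Reproducibility and experiment sizes

Every simulation function derives independent sub-streams (allele
frequencies, eQTL cohort, GWAS cohort, allele labels) from one integer
seed, so any table is exactly reproducible in isolation and cohorts stay
independent. The Monte-Carlo experiments use sizes chosen to estimate
each quantity to well under its decision margin: 2000 replicates for
type-I error (binomial SE ≈ 0.005 at 0.05), 1000 per power-grid point,
500 for Wald-ratio recovery, and 200 full-pipeline replicates for
causal-probe ranking. The calibration/power/recovery experiments run on
a reduced configuration (5 cis SNPs, no null probes) via a fast path
that computes only the causal pair's statistics — verified in the suite
to agree with the full study tables to 1e-12 — while the ranking
experiment runs the complete read–harmonize–test path at the default
generator.

## Known limitations

* No HEIDI-style heterogeneity filtering, LD clumping or colocalization:
  calls are single-instrument and linkage-susceptible by construction.
* rsID-only matching silently misses variants whose ids differ between
  deposits (merged ids, chr:pos keys).
* No allele-frequency-based rescue of palindromic SNPs; `"strict"`
  simply discards them.
* Gene identity is exact symbol match; no alias mapping between
  annotation vintages.
* Thresholding assumes the supplied panel probe counts are the right
  family sizes; when a file is already a filtered subset, `"infer"`
  over-corrects toward smaller families.
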