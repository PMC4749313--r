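---
title: "Statistical methods and synthetic-data calibration"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Statistical methods and synthetic-data calibration}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cnvdiet)
```

This vignette records the exact statistical definitions the package
implements, its degenerate-case policies, its coordinate conventions
and the calibration of the synthetic-data generators. The test suite
cross-checks every from-scratch statistic against an independent
oracle (closed forms, exact enumeration, or the base-R reference
implementation); this document states what those oracles verify.

## Robust rank order (Fligner–Policello) test

For samples $x_1,\dots,x_n$ and $y_1,\dots,y_m$, the placement of
$x_i$ is

$$P(x_i) = \#\{j : y_j < x_i\} + \tfrac12\,\#\{j : y_j = x_i\},$$

and symmetrically for $P(y_j)$; ties count one half, and the placement
sums are conserved: $\sum_i P(x_i) + \sum_j P(y_j) = nm$ (asserted at
run time). With $\bar P_x,\bar P_y$ the mean placements and

$$V_x = \sum_i (P(x_i) - \bar P_x)^2, \qquad
  V_y = \sum_j (P(y_j) - \bar P_y)^2,$$

the statistic is

$$z = \frac{\sum_j P(y_j) - \sum_i P(x_i)}
          {2\sqrt{V_x + V_y + \bar P_x \bar P_y}},$$

referred to the standard normal (two-sided). A positive $z$ means the
*second* sample is stochastically larger. Unlike the rank-sum test,
the denominator is estimated separately per sample, so the test does
not assume equal shapes or variances — the relevant situation here,
where the selection-regime group is much tighter than the drift
group.

**Exact oracle.** `fligner_policello_exact()` enumerates all
$\binom{n+m}{n}$ relabelings (bounded at $n+m \le 14$) and reports
$p = \Pr(|z_\text{perm}| \ge |z_\text{obs}|)$ with a $10^{-12}$ tie
guard. The suite checks that the asymptotic $p$ tracks the exact one
(median $|\Delta p| < 0.05$ over hundreds of small continuous
datasets) and that the effect sign always agrees.

**Degenerate cases.** Complete separation makes $V_x = V_y =
\bar P_x \bar P_y = 0$ with a nonzero numerator: the result is flagged
`degenerate`, $z = \pm\infty$, $p = 0$. A $0/0$ statistic (possible
only under separation-with-ties edge cases) yields $z = 0$, $p = 1$.
Two identical constant samples are *not* degenerate: tied placements
keep $\bar P_x \bar P_y > 0$, giving a clean $z = 0$, $p = 1$.

## Fligner–Killeen variance test

The normal-scores variant, matching `stats::fligner.test` to
$10^{-12}$: pooled ranks $r_i$ of $|x_i - \tilde x_{g(i)}|$ (absolute
deviations from the group medians) are transformed to scores
$a_i = \Phi^{-1}\!\big(\tfrac12 + \tfrac{r_i}{2(N+1)}\big)$, and

$$X^2 = \frac{\sum_k n_k (\bar a_k - \bar a)^2}{\operatorname{var}(a)}
  \sim \chi^2_{k-1}.$$

The statistic is location- and scale-invariant. When every
within-group deviation is zero (all groups constant) the statistic is
undefined; the result is flagged degenerate with $p = 1$ (no evidence
of unequal spread). Calibration (null rejection rate at
$\alpha = .05$ within $[0.041, 0.059]$ over 5000 replicates) and power
(SDs 2.2 vs 4.2 at $n = 34/46$, the *AMY2B* group configuration,
$\ge 80\%$) are asserted in the acceptance tests.

## Welch *t* and ordinary least squares

Both are implemented in closed form (Satterthwaite degrees of freedom;
normal equations with $n-1$ residual SD) and cross-checked against
`t.test()` and `lm()`/`summary.lm()` to $10^{-12}$. Constant-sample
Welch inputs are flagged degenerate ($p = 1$ for equal means,
$p = 0$, $t = \pm\infty$ otherwise). OLS requires at least three
points and a non-constant predictor; $R^2$ is clamped to $[0,1]$
against roundoff.

## aCGH focal-gene outlier

Per-site mean log2 ratios of breed $y$ are regressed on breed $x$ over
the *null* sites — sites with at least one sample from each breed,
excluding the focal gene. The focal deviation is reported as

$$z = \frac{r_\text{focal} - \bar r}{s_r},$$

the focal residual standardized by the null-residual moments
($n - 1$ SD). The focal point never enters the fit; the suite proves
the exclusion is real by showing the fit changes when the focal point
is appended. $z$ is invariant to shifting all $y$ means. A perfect
null line has $s_r = 0$ and is flagged degenerate with $z = 0$ when
the focal point lies on it. Copy numbers convert to expected log2
ratios by `cnv_to_log2(cn, reference)` $= \log_2(\text{cn} /
\text{reference})$; because vertical residuals are not symmetric in
the two breeds, `run_acgh()` reports both orientations.

## ΔDAF introgression scan

Derived allele frequencies are counted over non-missing chromosomes
(dosage 0/1/2 per individual; missing genotypes drop out of the
denominator, never imputed). Per locus,
$\Delta\text{DAF} = \text{DAF}_\text{dogs} - \text{DAF}_\text{wolves}$
with dogs pooled across breeds. Over all usable loci the scan takes
the mean $\mu$ and SD $\sigma$ ($n-1$) and flags ancestry-informative
SNPs (aiSNPs) outside $\mu \pm 2\sigma$ — a deliberately asymmetric
two-sided rule: published thresholds of this form, e.g. $(0.557,
-0.579)$, are not symmetric about zero, and
`invert_thresholds()` recovers the moments they encode:
$\mu = (u + \ell)/2 = -0.011$, $\sigma = (u - \ell)/4 = 0.284$. The
builder and its inverse round-trip to machine precision on any scan.

Gene regions span the interval between the flanking transcription
start sites, padded by 500 kb per side (the typical length of
wolf-introgressed haplotypes in dogs), clamped at zero. At each
region aiSNP, the *wolf allele* is the allele at higher wolf
frequency (derived when wolf DAF $> 0.5$, ancestral when $< 0.5$;
exactly $0.5$ resolves deterministically to the derived allele with a
tie flag and a warning). Breeds are ranked by their mean wolf-allele
frequency over the region's aiSNPs. `chromosome_control()` runs a
Welch test of one chromosome's ΔDAF values against the genome-wide
set as a sanity check that no single chromosome drives the scan.

## Coordinate and data conventions

- Locus positions are 1-based at every interface (VCF convention).
- Regions are 0-based half-open internally; a locus at position $p$
  lies in $[s, e)$ iff $s \le p - 1 < e$. BED files are read and
  written in 0-based half-open form.
- Raw diploid copy-number calls are rounded half away from zero
  ($\operatorname{sign}(x)\lfloor |x| + 0.5 \rfloor$) exactly once, at
  ingestion; aggregated literature calls may arrive pre-rounded
  without raw values, which are kept as `NA`.
- In a VCF, the ancestral allele comes from an INFO tag (default
  `AA`); records whose tag matches neither REF nor ALT are excluded
  with a warning, and dosages are flipped to derived-allele counts
  when the ancestral allele is ALT.

## Synthetic-data generator calibration

Generator defaults are fixed design choices, set before any acceptance
run, at the scale of the ddPCR study panel they emulate:

- `default_breed_config()`: five breeds, 80 samples; two high-starch
  breeds under "selection" (means 11.1 and 10.7, SDs 2.7 and 1.7) and
  three low-starch breeds under "drift" (means 8.3, 7.8, 6.1, SDs
  3.4–5.0), with per-breed latitudes and nutrient categories.
  Measurement noise SD 0.3 matches the scale of reported ddPCR
  technical errors. True copy numbers are truncated normal at zero.
- `simulate_acgh()`: 156 null sites on $y = x$ with vertical noise SD
  0.15 and a focal offset of 0.9, giving an expected $|z|$ of
  $0.9/0.15 = 6$, the size of deviation the aCGH analysis is meant to
  detect. The focal point carries no extra noise (its offset *is* the
  ground truth) and per-sample jitter is centered within site so site
  means are exact.
- `simulate_genotypes()`: wolf DAFs are Beta(1, 1); the shared dog
  base frequency adds Normal(0, `divergence_sd`) divergence, clamped
  to $[0,1]$. The default `divergence_sd = 0.35` was calibrated once
  so the genome-wide ΔDAF SD on the default panel ($\approx 0.29$)
  matches the $\sigma = 0.284$ implied by published scan thresholds;
  clamping shrinks the realized spread below the nominal SD (0.25
  yields only $\approx 0.23$). Introgression replaces each haplotype
  of the target breed with a wolf-frequency draw with probability
  `introgression_fraction`; planted aiSNPs get dog/wolf frequencies
  $0.5 \pm \text{effect}/2$ and coordinates inside (or beyond) a
  supplied gene region.
- `simulate_latitude_dataset()`: a shared mean copy number with a
  latitude-dependent SD (default step 4.4 → 5.3 at 40° absolute
  latitude), emulating the species-wide pattern of
  latitude-independent means with latitude-dependent spread.

Every generator is a pure function of its arguments including the
seed: the caller's RNG state is saved and restored, and
`run_simulate()` scenario bundles replay byte-identically from the
same seed.

## A compact end-to-end run

```{r example, eval = FALSE}
sim <- simulate_breed_cnv(seed = 2024)
compare_by_diet(sim$calls, sim$breeds, "AMY2B", "starch", threshold = 10)

region <- gene_region("AMY2B", "chr6", 2000000L, 3000000L)
g <- simulate_genotypes(introgressed_breed = "BreedD",
                        introgression_fraction = 0.5,
                        n_planted_aisnps = 3L,
                        planted_region = region, seed = 2024)
dogs <- g$dosage_by_pop[setdiff(names(g$dosage_by_pop), "wolves")]
fw   <- derived_allele_freq(g$dosage_by_pop$wolves)
scan <- delta_daf_scan(g$loci,
                       derived_allele_freq(do.call(cbind, dogs)), fw)
aisnps_in_region(scan, region)
```
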