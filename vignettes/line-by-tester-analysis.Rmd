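---
title: "Line x tester analysis of multi-environment maize trials"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Line x tester analysis of multi-environment maize trials}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lxtrial)
```

## The problem

Breeding provitamin A (PVA) biofortified maize hybrids requires choosing
*testers*: common inbred parents crossed to every candidate line so that the
lines' combining ability can be compared on a uniform genetic background. In
a line x tester design, `l` candidate lines crossed to `t` testers give
`l * t` testcrosses whose variation partitions into the lines' general
combining ability (GCA, reflecting additive gene action), the testers' GCA,
and line x tester specific combining ability (SCA, non-additive action).
`lxtrial` implements the full analysis of such a trial evaluated in several
environments — the combined analysis of variance, method-of-moments variance
components, GCA/SCA effects with standard errors, Baker's predictability
ratio, entry-mean repeatability, standard heterosis against the inter-tester
hybrid, genotypic and phenotypic trait correlations, and per-tester genetic
variances — together with a synthetic trial generator whose ground truth
makes every estimator testable.

The default study conditions mirror a published evaluation of 60
PVA-enriched tropical inbred lines crossed to two testers of contrasting PVA
level: 120 testcrosses plus the T1 x T2 inter-tester hybrid and three
commercial checks (124 entries), grown in two replicates of a 31 x 4
resolvable incomplete-block (alpha-lattice) layout, in eight environments
for agronomic traits and four for carotenoids.

## The model

A plot value is modelled as

y = mu + g_line + g_tester + s(line, tester) + E_env + R_rep(env) +
B_block(rep, env) + (gE)_line,env + (gE)_tester,env + (sE)_line,tester,env +
eps

with hybrids fixed and environment, replicate, block and the x environment
interactions random. On a balanced trial the combined ANOVA partitions the
plot variation into Env, Rep(Env), Block(Env x Rep), Hybrid — split into
Testcross, Line (GCA), Tester (GCA) and Line x Tester (SCA) — the matching
x Env interactions, and Error. All factorial strata are closed-form
balanced-design sums of squares; the incomplete blocks and the residual are
separated by sequential least squares within each environment (blocks fitted
after replicates and entries), which reproduces the table layout used for
lattice trials without re-implementing a proprietary mixed-model solver.
A two-stage lattice-adjusted analysis is intentionally not attempted: block
effects enter only as the displayed Block(Env x Rep) stratum, and the error
mean square is the block-adjusted residual.

### Error terms

The source publication does not state its F-test denominators. Because
environments are random, each genetic source is tested against its own
x environment interaction (Line vs Line x Env, Tester vs Tester x Env,
Line x Tester vs Line x Tester x Env, Hybrid vs Hybrid x Env, Testcross vs
the pooled testcross x Env interaction); design terms and the interactions
themselves are tested against the pooled error. With a single environment
every genetic source falls back to the pooled error.

### Variance components and derived statistics

Method-of-moments estimators equate observed mean squares to their balanced
expectations:

* `v_sca = (MS_LxT - MS_LxTxE) / (r e)`
* `v_gca_line = (MS_Line - MS_LinexE) / (r t e)`
* `v_gca_tester = (MS_Tester - MS_TesterxE) / (r l e)`
* x Env components from contrasts with the three-way interaction, and
  `v_residual = MS_error`.

Negative estimates are truncated to zero and flagged, never silently.
Standard errors use the large-sample variance of a linear combination of
independent mean squares, `Var(MS) = 2 MS^2 / (df + 2)`. REML would estimate
the same estimands on balanced data; the closed forms are used because they
are exactly testable against brute-force least squares.

Derived statistics follow the field's conventions:

* **Baker's ratio** `2(MS_line + MS_tester) / (2(MS_line + MS_tester) +
  MS_sca)` — the share of combining-ability variation that is general;
  values near 1 mean hybrid performance is predictable from GCA alone.
* **Repeatability** (entry-mean broad-sense heritability)
  `H = v_g / (v_g + v_ge / e + v_residual / (e r))` with
  `v_g = v_gca_line + v_gca_tester + v_sca` and `v_ge` the sum of the three
  x Env components. The source publication does not print its repeatability
  formula; this entry-mean definition is the package's documented choice.
* **Proportional contributions** of Line, Tester and Line x Tester are
  reported under two labelled conventions: shares of the testcross sum of
  squares (which add to 100 exactly) and shares of the truncated variance
  components. Published "proportional contribution" figures computed by
  other software are not always reproducible from printed mean squares;
  both definitions are therefore emitted and neither is forced to match.
* **Additive vs non-additive share**
  `2(v_gca_line + v_gca_tester) / (2(v_gca_line + v_gca_tester) + v_sca)`,
  the factor 2 converting GCA variance to additive variance under the
  testcross model.

### GCA/SCA effects

With complete pooled testcross means, GCA and SCA are the row/column/grand
mean decomposition — identical to constrained least squares under zero-sum
constraints (a property test in the suite checks this to 1e-10). Standard
errors use the random-environment denominators
(`se_gca_line = sqrt(MS_LinexEnv / (r e t))` and so on); per-effect t tests
carry the denominator's degrees of freedom. With two testers the GCA
estimates are exact mirror images, matching the paired-column layout used in
tester tables.

### Heterosis and check comparisons

Standard heterosis is `H = 100 (F1 - CK) / CK` against the inter-tester
hybrid. Entries are compared with a named check by a two-sided LSD at
alpha = 0.05 built from the combined-analysis pooled error; no multiplicity
correction is applied, matching the star-only reporting convention of
published tables.

### Genotypic and phenotypic correlations

Phenotypic correlations are product-moment correlations of testcross pooled
means over the environments where both traits are recorded. Genotypic
correlations are method-of-moments: `v_g` for each trait from the
entry-level identity `(MS_entry - MS_entryxEnv) / (r e)`, and the genetic
covariance from the same identity applied to the sum trait,
`cov_g = (v_g(x + y) - v_g(x) - v_g(y)) / 2` — algebraically equal to the
mean-cross-product route (an internal oracle asserts this to 1e-8).
Estimates outside [-1, 1] are possible in small samples and are returned
with an `out_of_bounds` flag; non-positive genetic variances make the
correlation undefined and raise an error rather than returning a number.

## The synthetic trial generator

`simulate_trial()` draws every effect of the model above as an independent
Gaussian at its configured variance. Two conventions matter:

* **Centering.** Line GCA, tester GCA and the SCA matrix are centered (sum
  zero; SCA row and column sums zero) so the stored ground truth is exactly
  the estimand of the closed-form decomposition. The x environment
  interactions, replicates, blocks and residuals are left as drawn:
  centering an interaction across the environment margin would remove its
  contribution to the main-effect mean squares and bias the
  method-of-moments estimators (for example `E[(MS_LxT - MS_LxTxE)/(r e)]`
  would fall below `v_sca` by `v_sca_env / e`). With iid draws the classical
  expected mean squares hold and the estimators above are unbiased — the
  parameter-recovery tests rely on this.
* **Carotenoid structure.** Rather than simulating five carotenoids
  independently, each genotype receives a total-carotenoid genetic value and
  a biosynthetic branch share: the beta-branch (beta-cryptoxanthin,
  alpha-carotene, beta-carotene) versus the alpha/xanthophyll branch
  (lutein, zeaxanthin). The branch share carries the tester contrast (the
  high-PVA tester shifts flux toward the beta branch) and line-to-line
  variation; within-branch proportions are fixed. Plot-level carotenoid
  concentrations are shares of the plot's total-carotenoid value, so the
  provitamin A and total-carotenoid identities hold exactly by construction.
  The genetic yield deviation of each cell scales its total carotenoid
  through a dilution coefficient (negative: more grain, same pigment mass),
  which induces the negative genotypic yield-PVA correlation.

### Default calibration

`default_trial_config()` fixes the study conditions. Grand means sit at the
reported testcross means (grain yield 6190 kg/ha, the midpoint of the two
testers' reported means; days to anthesis 56.97; total carotenoid 31.4
ug/g DW giving a PVA mean near 11.5 ug/g, inside the reported 6.2-18.4
range). Residual variances reproduce the reported coefficients of variation
(e.g. yield CV near 17%, PVA near 10%). Genetic variances are set so that
line GCA dominates SCA (Baker ratios near the reported 0.87-0.99) and the
tester contrast matches the reported tester GCA magnitudes (about +/-110
kg/ha for yield via `v_gca_tester = 12000`; the beta-branch tester shift of
0.048 yields a PVA tester GCA near +/-1.25 ug/g). The dilution coefficient
-0.0037 ug/g per kg/ha places the expected genotypic yield-PVA correlation
at about -0.25, the reported value; over 100 simulated trials the mean
estimated correlation falls in [-0.35, -0.15].

Checks and the inter-tester hybrid are carried in the book but excluded
from the line x tester genetic partition. Check entry effects are drawn with
variance `v_gca_line + v_sca` (hybrids of typical variability); the
inter-tester hybrid sits at the trait mean (the two testers' GCAs cancel by
centering), so standard heterosis of an average testcross is near zero.
Scores (plant/ear aspect) are latent Gaussians clipped to [1, 5] and
analysed as continuous, as the published ANOVA does; yields and
concentrations are clipped at zero (vanishingly rare at the default
variances). Grain weight and moisture are back-computed from the simulated
yield so that the standard moisture adjustment reproduces the simulated
yield exactly; days to silking is the sum of the simulated days-to-anthesis
and anthesis-silking-interval values.

The layout is a randomized resolvable incomplete-block design: entries are
re-randomized into blocks of `k` within every replicate of every
environment. The concurrence-optimizing construction of a true alpha design
is not implemented — no analysis step here exploits concurrence, only
resolvability.

### What the generator does not emulate

Real trials are unbalanced (lost plots), spatially autocorrelated, and
carotenoid measurement error is right-skewed and heteroscedastic; none of
that is simulated. Passing the recovery tests shows the estimators are
correct under the stated model, not that the model captures every feature
of field data. The missing-data policy is deliberately strict: analyses
require complete testcross x environment cells within the environments
where a trait was measured at all, and abort with named cells otherwise —
imputation would invent behaviour the published analysis never defined.

## Numerical conventions

* Pooled testcross means are plot-level means by default; the mean of
  environment means is also available (`pooling = "env_mean"`), the two
  being equal on balanced data.
* Reports round half-to-even at two decimals (`round_report()`), stated once
  and used everywhere; significance is rendered `*` (p < 0.05) and `**`
  (p < 0.01).
* Degrees of freedom are always the algebraic values; one published table
  prints a Hybrid x Env row with one df fewer than `(H - 1)(e - 1)` and a
  correspondingly larger error df, which the package does not reproduce.
* Repeatability and the additive share use truncated (non-negative)
  components; the recovery tests compare the raw (untruncated) component
  estimates, which are the unbiased ones, and allow repeatability — a ratio
  of estimates with a small finite-sample bias — a recovery tolerance of
  0.05.

## Problem sizes used by the test suite

Parameter-recovery and calibration suites run at the full study design
(60 lines x 2 testers x 8 environments x 2 replicates): 200 simulations for
component recovery, 500 for the size of the SCA F-test under `v_sca = 0`
(nominal 5%), and 100 for the yield-PVA correlation calibration. Module
property tests use smaller designs (4-40 lines, 2-4 environments) with
50-150 replicates each, chosen so the whole suite completes in a couple of
minutes while Monte-Carlo standard errors stay well inside the asserted
tolerances.

## Known limitations

* Only balanced trials are analysed; there is no general mixed-model engine,
  spatial correction, or lattice-adjusted two-stage analysis.
* With `t = 2` the tester GCA mean square has a single degree of freedom, so
  `v_gca_tester` is estimated with very low precision — its standard error
  makes that visible rather than hiding it.
* Genotypic correlations can leave [-1, 1] and genetic variances can be
  estimated non-positive in small or noisy trials; both situations are
  signalled, not patched.
* Reciprocal effects are not modelled (reciprocal crosses are assumed
  bulked), and no Griffing-style diallel analysis is provided.
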