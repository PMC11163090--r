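---
title: "Disproportionality signal detection with pvsignal: models, choices, limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Disproportionality signal detection with pvsignal}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pvsignal)
```

## The problem

Spontaneous reporting systems such as FAERS collect adverse-event reports
without denominators: there is no count of patients exposed, only reports.
Disproportionality analysis sidesteps the missing denominator by asking
whether a drug–event pair is reported *more often than independence of the
drug and event margins would predict*. `pvsignal` implements the four
indices in routine pharmacovigilance use — ROR, PRR, EBGM and IC — on top
of a reproducible FAERS ingestion and cohort-building layer, and combines
them with the conservative rule that a pair is a signal only when **all
four** indices pass their thresholds with their minimum report counts.

The package was built around a concrete case study: pancreatitis reported
with the three newer antidiabetic drug classes (GLP-1 receptor agonists,
DPP-4 inhibitors, SGLT2 inhibitors) in the 2019–2021 FAERS window, with a
within-class comparison of the GLP-1 RAs against exenatide as reference
drug. The published class-level estimates for that study ship as
`reference_values()` and serve as worked-example inputs for the decision
rule and the descriptive arithmetic; reproducing them from raw data
requires the actual FAERS quarters and the original dictionary and
deduplication choices, so they are treated as external reference points,
not as test targets for the synthetic pipeline.

## From files to a cohort

FAERS quarters arrive as "$"-delimited ASCII tables. The reader
(`read_ascii_table()`) insists on the mandatory columns per table, maps
empty fields to `NA`, validates DEMO dates against the calendar (an
impossible date like `20190230` becomes missing, with a warning, and the
row is kept), and preserves unknown columns untouched. The native dialect
has no escape convention, so a literal `$` inside a field cannot
round-trip; the writer substitutes it (default: removes it) and warns.
Partial dates (`yyyymm`, `yyyy`) are legal FAERS content and keep their
derivable year.

Cohort construction makes four decisions that the raw format leaves open:

* **Report year.** A report's year comes from the event date when one is
  present, else from the FDA receipt date. Reports with no derivable year
  are excluded from the windowed cohort and tallied — the study window is
  an inclusion criterion, and a report that cannot be dated cannot satisfy
  it.
* **Deduplication.** FAERS cases carry versions (`caseid`,
  `caseversion`) *and* true duplicates. The default rule is two-stage:
  first keep only the highest version of each case, then collapse rows
  identical on (case, event date, set of preferred terms), breaking ties
  deterministically by the largest report identifier. A `"literal"` mode
  that drops only exact (report id, event date, term) duplicates is kept
  for sensitivity analysis; because report identifiers are unique, it
  removes almost nothing, which is precisely what it is there to
  demonstrate.
* **Primary suspect only.** Only drugs in the PS role define exposure;
  suspect-secondary, concomitant and interacting drugs never contribute.
  A report whose PS drugs map to two classes counts for each class
  independently (the usual one-row-per-drug convention); the audit trail
  counts such reports.
* **Exact term matching.** The target event is matched exactly (after
  trimming, whitespace collapsing and case folding): `"Pancreatitis
  acute"` is *not* the target `"pancreatitis"`. A single preferred term is
  a deliberately blunt instrument; passing a vector of terms turns on
  term-list matching for users who want an SMQ-like broader net.

Ages convert to years by unit (months /12, weeks /52, days /365.25, hours
/8766, decades ×10) and implausible results (> 120 years) become missing.
Age bins are 0–18, 19–30, 31–40, 41–50, 51–60, 61–70, > 70 — decade bins
above 50 where reporting concentrates, a wider first bin because pediatric
type-2 diabetes reports are rare.

Every removal is audited: the cohort's input count always equals its
output count plus the per-stage exclusions, and the property suite checks
this identity on generated data.

## The frequentist indices

With 2x2 cells `a, b, c, d` (exposure × event, comparator = every other
report in the cleaned window — the full database background, not just the
studied classes):

$$\mathrm{ROR} = \frac{ad}{bc}, \qquad
\mathrm{PRR} = \frac{a/(a+b)}{c/(c+d)}$$

both with Wald 95% intervals on the log scale. When any cell is zero, 0.5
is added to all four cells for both the point estimate and the interval
(Haldane–Anscombe), and the result is flagged `correction_applied`. The
interval level is fixed at 95% (z = 1.96), matching the convention of
every published interval the package mirrors. The signal rule applies the
ROR threshold to the point estimate — the rule as usually stated — with a
`ror_rule = "ci_lower"` switch for the stricter lower-bound variant.

## The Bayesian indices

Expected counts come from the margins of the drug-by-event grid,
$E_{ij} = n_{i\cdot} n_{\cdot j} / n_{\cdot\cdot}$; optional stratification
(sex, age bin, year) sums stratum-wise expectations. Note a structural
bias that matters when interpreting simulations: a genuinely elevated pair
inflates its own row and column totals, so its estimated expectation
exceeds the no-signal expectation and the observed-to-expected ratio
lands *below* the generating relative risk. This is a property of the
margin-based baseline itself, not of the estimators.

**EBGM.** The rate ratio λ of each pair is given DuMouchel's
two-component gamma mixture prior
$\lambda \sim p\,\Gamma(\alpha_1, \beta_1) + (1-p)\,\Gamma(\alpha_2, \beta_2)$.
Marginally each count is then a two-component negative-binomial mixture,
and the five hyperparameters are fitted by maximum marginal likelihood on
the whole grid. The fit uses expectation-maximization: the E-step computes
each pair's posterior component membership, the M-step refits each
component by weighted negative-binomial likelihood (Nelder–Mead on the
log scale) and sets the weight to the mean membership. EM was chosen over
direct quasi-Newton search because the observed-data log-likelihood is
guaranteed non-decreasing and the procedure is deterministic; direct BFGS
on this surface can drive the mixture weight to a boundary and discard
the diffuse component entirely, which catastrophically over-shrinks true
signals. Shapes and rates are clamped to `exp(±12)` — a gamma component
with shape `1.6e5` is already numerically a point mass, and larger values
only destabilize the quantile routines. Convergence is declared when the
transformed parameter vector moves less than `tol = 1e-6` between
iterations (cap `max_iter = 500`); a fit that does not converge is
returned with `converged = FALSE` and a warning, never silently.
DuMouchel's published defaults (α₁ = 0.2, β₁ = 0.1, α₂ = 2, β₂ = 4,
p = 1/3) are the starting point and the package's default prior.

The posterior for a pair with count *n* and expectation *E* is again a
two-component gamma mixture, with components
$\Gamma(\alpha_k + n, \beta_k + E)$ and updated weights.
$\mathrm{EBGM} = 2^{\,\mathbb{E}[\log_2 \lambda \mid n, E]}$ has a closed
form through digamma functions; the tests verify it against independent
numerical quadrature of the unnormalized posterior to 1e-4 over a grid of
(n, E). EB05/EB95 are posterior quantiles solved by root-finding on the
mixture CDF, bracketed by the component quantiles (the bracket is widened
by 0.1% because `qgamma`/`pgamma` round-trip error under near-degenerate
components can otherwise leave both ends on the same side of the target).

**IC.** The information component uses the closed form
$\mathrm{IC} = \log_2\frac{n + 0.5}{E + 0.5}$ with credibility limits
IC025/IC975 taken as log₂ of the 2.5th/97.5th percentiles of
$\Gamma(n + 0.5,\, E + 0.5)$ — the standard shrinkage formulation used by
the WHO collaborating centre. It is exact, cheap, monotone in *n* and *E*,
and well defined at *n* = 0.

The two Bayesian indices deliberately answer the same question with
different machinery: EBGM borrows strength across the whole grid through
a fitted prior, IC applies a fixed, data-independent shrinkage. Agreement
between them is part of what the all-four rule buys.

## The signal rule

Defaults: ROR > 1 with n ≥ 2; PRR > 2 with n ≥ 3; EBGM ≥ 2 with n ≥ 1;
IC > 0 with n ≥ 1; signal = conjunction of the four. The EBGM threshold is
inclusive ("two or more") while ROR/PRR/IC are exclusive ("more than") —
the tests pin this boundary behaviour explicitly. All thresholds and
minimum counts are configurable through `signal_criteria()`; raising any
of them can only remove signals (a property the suite checks), so the
defaults are the *most permissive* version of the rule and every reported
signal survives any stricter variant a reviewer might prefer.

Seriousness in the descriptive tables counts a case as serious when it
carries at least one outcome in {DE, DS, HO, LT, RI, CA}; "other" (OT) is
not serious. Published seriousness percentages are often computed over
denominators that cannot be reconstructed from the printed tables, so the
package always states its own denominator (all cases for the exposure) in
the output metadata.

## The synthetic generator

`generate_database()` emulates what the analysis assumes about FAERS: a
drug-by-event count grid that is independent except for injected
multiplicative signals, expanded into schema-faithful DEMO/DRUG/REAC/OUTC
quarters. Pair counts are drawn
$n_{ij} \sim \mathrm{Poisson}(N\, w_i\, w_j\, \mathrm{RR}_{ij})$ with
margin weights from a seeded symmetric Dirichlet; each case then receives
demographics, dates (event date uniform in its year, receipt date lagged
geometrically with mean 30 days), hospitalisation-heavy outcome codes, and
— at configured rates — a superseded earlier case version, a duplicate
emission under a new report identifier, and missing sex/age/dates.

The reference scenario (the defaults) is a 200 x 100 grid with 200,000
expected reports over 2019–2021, one signal at relative risk 10 placed
automatically on a pair whose expected count is near 20, choosing among
candidates the pair with the most *balanced* margins so that the signal's
own margin inflation (see above) is as small as the grid allows. Rates:
2% duplicates, 3% versions, 14% missing sex (the ballpark of real FAERS
demographic missingness), 5% missing dates, 15% missing age. The `"null"`
preset (50 x 30, 50,000 reports, no injection) supports calibration
checks; the `"stress"` preset widens the year span beyond the analysis
window, raises all corruption rates and turns on multi-drug/multi-term
cases. Everything derives from one mandatory seed, and identical configs
produce byte-identical files — the determinism the hygiene tests assert.

What the generator does *not* emulate: drug-name noise (misspellings,
salts, combination products), reporting trends over time, correlated
missingness, and the long-tailed real-world margin distribution beyond
what a Dirichlet draw gives. Passing tests on synthetic data therefore
demonstrate the *pipeline's* correctness and the *estimators'*
calibration under the stated model, not robustness to real FAERS name
normalization, which remains the analyst's responsibility via the
user-overridable drug dictionary.

## Problem sizes and runtime choices

The test suite runs the reference scenario once end-to-end (about 15,000
observed pairs from 200,000 reports), refits hyperparameters from a known
prior at 50,000 simulated pairs, checks interval coverage on 2,000
simulated null tables, and uses small handcrafted bundles everywhere
correctness is a matter of counting. These sizes keep the whole suite in
the low minutes on one core while leaving the stochastic checks enough
resolution: at 50,000 pairs the hyperparameter refit lands within a few
percent of the generating values, comfortably inside the 20% band the
acceptance criterion allows, and the injected-signal EBGM check spans the
contamination-adjusted range [8, 12] discussed above.

## Known limitations

* Margin-based expectations are biased against strong signals in small
  databases (self-contamination); stratified or signal-excluded baselines
  would mitigate this but are deliberately out of scope.
* The EBGM machinery covers single drug–event pairs only; multi-item
  (interaction) extensions are not implemented.
* Exact Fisher-type intervals, chi-square statistics and time-scan
  methods are intentionally absent: the four implemented indices define
  the decision rule.
* PT matching is literal; no MedDRA hierarchy traversal is attempted
  (licensing aside, the package never sees the hierarchy).
* The within-class comparison counts a report exposed to both the drug
  and the reference drug in both arms; such reports are rare and the
  behaviour is documented rather than special-cased.
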