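---
title: "Auditing cause-of-death certification quality: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Auditing cause-of-death certification quality: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Mortality statistics stand on the underlying cause of death (UCOD): the
condition or injury that initiated the chain of events leading to death,
recorded on the lowest used line of Part 1 of the international medical
certificate of cause of death. When certificates carry common certification
errors — several conditions crammed onto one line, missing disease time
intervals, clinically impossible causal chains, "cardiac arrest" as the
underlying cause — coders cannot select the correct UCOD and the resulting
cause-of-death statistics lose their value for public-health planning.

`certaudit` implements a rule-based audit of such certificates: seven
deterministic error detectors, a weighted composite error score, group-level
quality tables with percentage-point improvement columns, and a
proportional-odds ordinal regression of the error score. Because
individual-level certification records from national registries are not
publicly deposited, the package also ships a seeded synthetic-certificate
generator whose defaults emulate a three-arm quality-improvement evaluation
(paper-based certification before any intervention; an online certification
system; the online system plus certifier training, with arm sizes
300/900/900). Every pipeline stage is therefore testable end to end.

## The error taxonomy and score

Four **major** error types (two points each) impair UCOD selection directly:

* *multiple causes per line* — a Part 1 line splits on a conjunction
  (";", ",", " y ", " con ", " and ") into two or more condition phrases;
* *missing time interval* — a used Part 1 line lacks a parseable
  "value;unit" interval. Part 1 only: intervals there are the mandatory
  check on the reported sequence, and the online systems this audit targets
  make them required fields;
* *incorrect sequence* — an adjacent pair of used lines is not in the
  reflexive transitive closure of a configured cause→consequence relation
  over condition categories, or the UCOD's category cannot initiate a chain
  (e.g. systemic infection);
* *ill-defined UCOD* — the lowest used line matches a lexicon of modes of
  dying, organ failures, symptoms/signs and shock.

Three **minor** error types (one point each): *blank lines* strictly inside
the causal chain (a leading blank is reported as a structural validation
finding instead — the error is scoped to gaps *within* the sequence);
*abbreviations* anywhere in the cause text (a configured token list plus any
all-capitals token of 2–6 letters off a whitelist); and *additional errors*,
an aggregate of four under-specification subtypes (external cause without
intent or mechanism, neoplasm without behaviour and site, age without
units, and "other": hypertension not marked essential/secondary, diabetes
without type, or a usable UCOD recorded in Part 2 beneath an ill-defined
Part 1).

Each error type counts once per certificate regardless of how many lines
exhibit it, and the additional-errors type contributes one point however
many subtypes fire. This per-type counting is the only reading consistent
with an observed score range topping out in single digits; the theoretical
maximum is 11 (4×2 + 3×1) and no truncation is applied. The weights are
arguments of `score_profiles()` for sensitivity analysis; 2/1 is the
default and the published convention.

All lexicon matching operates on normalized text (lowercase, Spanish
diacritics stripped, whitespace collapsed). The shipped lexicons are
Spanish with English aliases and are deliberately small, exact-match and
fully overridable (`read_rule_config()`): they are an explicit,
reproducible stand-in for the clinical judgment a single trained human
reviewer applies, which is not itself published. The ~13-category causal
relation is likewise a conservative automation of "clinically improbable":
unmapped conditions are treated as compatible and never trigger the
sequence flag, so enlarging the lexicon can only be done deliberately.

## The synthetic-data generator

`sample_cohort()` draws, per certificate: attributes (age band, sex,
certifier seniority, speciality, facility level, months since training)
from configured category weights; seven error flags, independently, with
per-arm base probabilities on the logit scale; and then **renders** a
certificate whose content manifests exactly the planted flags under the
default rule configuration. `assess(render(profile)) == profile` is the
module's central contract, tested exhaustively over all 2^7 flag
combinations crossed with the feasible subtypes.

Design choices worth knowing:

* **Independence of error types.** The study conditions give per-arm
  prevalences for each error type but no correlation structure, so flags
  are drawn independently given age. A consequence: quantities that depend
  on the *joint* distribution — most visibly the share of fully correct
  certificates — are not reproduced. Real errors are positively correlated
  (the same negligent certificate accumulates several), so the generator's
  correct-share per arm (about 0/14/24%) undershoots the published
  0/30/43%. The correct-share improvements are therefore verified as
  printed-table arithmetic, not as generator output. An optional per-doctor
  random intercept (`doctor_sd`) exists for clustering/correlation
  sensitivity experiments and is off by default.
* **Age effect.** Every error logit carries a per-year increment of
  log(1.009), centred at the cohort's expected age (~62 years under the
  default age distribution) so that the arm base probabilities remain the
  marginal prevalences. Uncentred, a per-year effect would shift every
  prevalence by several points.
* **GBD group coupling.** `gbd_group == "ill_defined"` exactly when the
  ill-defined-UCOD flag is planted, which makes "ill-defined causes have
  100% any-error" an analytic property rather than a sampling accident. The
  price is that the ill-defined GBD margin equals that error's prevalence
  (~39–52%) rather than the published attribute count; the other three GBD
  groups follow the published proportions conditional on the flag being
  false.
* **Subtype allocation.** The four additional-error subtypes are mutually
  exclusive per certificate (their published prevalences sum to the
  additional-errors prevalence). One combination is unrenderable: an
  external-cause subtype requires an under-specified injury as UCOD, which
  cannot coexist with an ill-defined UCOD. `render_certificates()` raises
  on it. The sampler instead allocates subtype probabilities separately in
  the ill-defined and non-ill-defined strata: with additional-error
  probability \(p_a\), ill-defined probability \(p_i\) and target subtype
  margins \(t_s\), the external subtype is drawn in the non-ill-defined
  stratum with probability \(t_{ext}/(p_a(1-p_i))\) and the remaining
  subtypes absorb the complementary mass in each stratum so that **all four
  marginal prevalences still match the targets exactly in expectation**
  (feasible whenever \(t_{ext} \le p_a(1-p_i)\), checked at configuration
  time).
* **Ages** are integer years drawn uniformly within the sampled band
  (top band 85–99); age units are always "years" unless the no-units
  subtype is planted, in which case the unit is absent. Months since
  training exist only in the online+training arm (the published training
  rows sum to exactly that arm's size), on a half-month grid so the
  <3 / 3–6 / >6 banding — boundaries inclusive in the middle band — is
  never ambiguous.
* **What is not emulated:** free-text clinical narrative beyond what the
  detectors read, certifier learning over time, correlation between
  attributes and error types beyond age, and the registry software itself
  (its hard constraints appear only as lower planted probabilities in the
  online arms, e.g. blank lines 11.3% → 0.2–0.3%). Passing tests on
  generator output therefore demonstrate the pipeline's internal
  correctness and calibration to the published margins — not performance
  on real certificates.

## The ordinal regression

The error score is ordinal, so the package fits the proportional-odds
(cumulative-logit) model
\[
\mathrm{logit}\, P(Y \le k \mid x) = \alpha_k - x'\beta ,
\]
under which \(e^{\beta_j} > 1\) means greater odds of a *higher* error
score than the reference category — the convention in which an online-system
odds ratio of 0.283 and an online+training odds ratio of 0.151 (against
pre-intervention) describe quality improvements, and the reciprocal
1/0.151 ≈ 6.6 reads as the odds of a *lower* score.

Implementation notes:

* Maximum likelihood by damped Newton–Raphson on the joint parameter vector,
  with the cutpoints reparameterized as \((\alpha_1, \log\Delta\alpha)\) so
  they stay strictly increasing. The analytic gradient is exact; the Hessian
  is a central finite difference of that gradient. Steps are halved until
  the log-likelihood does not decrease, so the likelihood trace
  (`fit$ll_trace`) is monotone by construction. Convergence is a gradient
  max-norm below 1e-8, cap 100 iterations; a capped fit returns
  `converged = FALSE` with a warning rather than failing.
* Covariance is the inverse observed information at the maximum, in the
  natural \((\alpha, \beta)\) parameterization. Both the standard error of
  the log-odds coefficient and the delta-method standard error of the odds
  ratio (`or_se = OR × se(β)`) are reported; published audit tables
  tabulate the latter. Wald p-values are two-sided; no multiplicity
  correction is applied (none is conventional in this single-model
  setting).
* Outcome levels with zero observations are collapsed away before fitting;
  levels with fewer than five observations are kept with a warning.
  Rank-deficient designs fail naming the aliased columns. Design columns
  are mean-centred internally for conditioning; cutpoints are shifted back.
* Numeric covariates enter continuously (age in years per year, using band
  midpoints {2, 24.5, 54.5, 69.5, 79.5, 90} when only bands are available);
  categorical covariates use reference-cell coding with the references
  pre-intervention / male / ill-defined / 0–5 years / general medicine /
  level I by default. `refit_with_reference()` switches a reference level;
  the maximized likelihood is invariant and OR(b vs new ref a) =
  OR(b)/OR(a) from the original fit — the construction behind contrast
  rows such as online+training versus online.
* The two-sample comparisons use Welch's unequal-variance t statistic with
  Welch–Satterthwaite degrees of freedom (the safer default when only
  "t-tests" is specified and arm variances differ), and the chi-square
  test is the plain Pearson statistic without continuity correction.

A known limitation, inherited deliberately: certificates cluster within
certifying doctors (in the emulated study ~1,257 doctors wrote the 2,100
sampled certificates), and the regression ignores that clustering, as the
published analysis did. Standard errors are therefore mildly optimistic;
the `doctor_sd` generator knob allows quantifying the effect.

## Numerical conventions and problem sizes

Percentages are computed on unrounded counts and rounded to one decimal
only at rendering (`render_table_text()`), matching the display precision
of published audit tables; percentage-point improvements are differences of
unrounded prevalences, rounded last. Degenerate inputs fail early with
named errors: zero chi-square margins, degenerate t-test groups, constant
outcomes, out-of-range percentages.

The test suite exercises the pipeline at the sizes a desk check needs:
the render/assess round trip over all 128 flag combinations × three
attribute draws; generator calibration at 20,000 certificates per arm
(every per-arm prevalence within one percentage point of its target);
arm-coefficient recovery from 200 replicates of 2,100-certificate cohorts
simulated at odds ratios 0.283/0.151 (joint 95% Wald coverage ≥ 90%);
bias below 0.05 log-odds at n = 10,000 over 100 replicates; and null
p-value uniformity over 500 replicates at n = 1,000. These sizes are the
package's reproducibility conditions and run in about two minutes.
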