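---
title: "Multi-source pharmacovigilance signal detection: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multi-source pharmacovigilance signal detection: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pvscreen)
```

## The problem

A *signal* is a statistical indication that a drug and an adverse event may
be associated before causality is established. No single real-world data
source suffices to find signals reliably: drug registries offer
clinician-verified exposure and ADR reports but modest sample sizes;
spontaneous reporting systems (SRS) offer scale but no denominators and
heavy reporting biases; electronic health records offer objective
laboratory trajectories but only for one institution's patients. `pvscreen`
chains the three: screen a registry for elevated relative risks, discard
pairs already on drug labels, demand confirmation by SRS
disproportionality, and annotate the survivors with laboratory evidence.
The setting the package emulates is biologic DMARDs and targeted therapies
in rheumatoid arthritis (RA) and ankylosing spondylitis (AS); the two
diseases are analysed as disjoint strata and merged only at the final
intersection, because drug usage and registry structure differ between
them.

## Registry screen

The counting unit is the *case*: one follow-up interval of one patient on
one drug. Only follow-ups with drug status "continued" from non-withdrawn
patients are eligible — a case must be attributable to an uninterrupted
exposure — and each follow-up is treated as an independent case. ADR
reports enter a case only when the reporter graded the drug–event
relatedness as *related* or *indeterminate*; severity and outcome are
deliberately ignored (presence/absence is the signal-detection datum).
Brand names (originators and biosimilars) are collapsed to generic names
and raw terms normalised to a preferred-term vocabulary before counting;
an unmapped brand or term is a hard error because a silent drop would bias
the denominator.

For each stratum and pair the 2×2 table (`a`, `b`, `c`, `d`; comparator =
cases on other drugs) gives

$$RR = \frac{a/(a+b)}{c/(c+d)},$$

with the Katz log-normal interval
$\exp(\ln RR \pm z_{1-\alpha/2}\sqrt{1/a - 1/(a{+}b) + 1/c - 1/(c{+}d)})$.
The Katz method was chosen as the standard risk-ratio interval for
independent binomial samples. No continuity correction is applied here:
`a = 0` reports RR = 0 with an undefined interval, and `c = 0` reports a
missing RR — corrections are confined to the SRS screen where a convention
is unavoidable.

**Significance rule.** A pair is flagged when RR > 1 *and* the unrounded CI
lower bound exceeds 1. Published tables in this literature often state the
looser rule "RR > 1" while printing intervals whose lower bounds all
exceed 1; the stricter rule reflects that table structure, and the literal
point-estimate rule remains available via `point_estimate_only = TRUE`.
Pairs need at least `min_count = 3` co-occurrences to be evaluated (the
default is configurable; published tables in this setting show counts of 4
and above). Both choices are package decisions where the field's practice
is not fully specified.

## Label exclusion

The knowledge base is a user-supplied table of (generic drug, preferred
term) pairs with provenance, standing in for a search of current drug
labels. Matching is exact on the normalised vocabulary and
disease-agnostic: a labelled pair is excluded from every stratum. The
operation is a pure partition of the significant pairs — novel ∪ excluded,
no overlap, input order preserved — and is idempotent.

## Spontaneous-report disproportionality

The counting unit is the distinct report; a report listing $k$ drugs and
$m$ events contributes to all $k \times m$ pairs, and duplicate mentions
collapse first. On the case/non-case table,

$$PRR = \frac{a/(a+b)}{c/(c+d)}, \qquad ROR = \frac{a/b}{c/d}, \qquad
IC = \log_2 \frac{a\,n}{(a+c)(a+b)}.$$

When any cell is zero, 0.5 is added to all four cells (Haldane–Anscombe)
and the result is flagged `corrected`. An exact algebraic identity ties the
three statistics together on uncorrected cells:
$a\,n - (a+b)(a+c) = ad - bc$, so sign(PRR − 1) = sign(ROR − 1) = sign(IC)
= sign(ad − bc). This is why frequentist disproportionality statistics
"agree" pair by pair in published analyses; the package's test suite
verifies the identity over 10,000 random tables.

**Decisions.** PRR and ROR get one-sided p-values from the Wald statistic
on the log scale (standard errors
$\sqrt{1/a - 1/(a{+}b) + 1/c - 1/(c{+}d)}$ and
$\sqrt{1/a + 1/b + 1/c + 1/d}$), adjusted by Benjamini–Hochberg. The IC
gets a Monte-Carlo posterior probability $P(IC \le 0 \mid \text{data})$
under independent conjugate posteriors — $p_{11} \sim
\mathrm{Beta}(a{+}1,\, n{-}a{+}1)$ for the joint cell and
$\mathrm{Beta}(a{+}b{+}1,\, c{+}d{+}1)$, $\mathrm{Beta}(a{+}c{+}1,\,
b{+}d{+}1)$ for the margins — and the Bayesian FDR at rank $i$ is the
cumulative mean of the sorted posterior null probabilities. Statistics and
FDR ranking are computed over the whole pair universe (disproportionality
marginals are global by definition); candidate annotation is a lookup. A
candidate absent from the SRS is annotated as such and counted
non-significant. The confirmation rule is *any of the three* at
FDR < 0.05.

**A calibration caveat.** The two FDR notions differ. Benjamini–Hochberg
controls the frequentist expectation $E[V/\max(R,1)]$ at the threshold even
under a complete null; the cumulative-mean Bayesian estimator controls the
*posterior-expected* fraction of nulls among declared pairs under its
mixture model. Under data that are entirely null, any Bayesian FDR
estimator will still declare a small fraction of pairs (the estimator
believes some posterior probabilities), and every declaration is then
false; in simulation the IC rule flags roughly 10% of pure-null pairs at
threshold 0.05 while PRR/ROR(BH) flag essentially none. This is a property
of the estimator class, not an implementation artefact, and is the reason
the package's calibration checks hold each rule to its own nominal
guarantee. In mixed universes with genuine signals — the operating regime
of the method — the three rules agree closely on strong pairs.

The one-sided Wald p-values are normal approximations on discrete counts;
their deepest tail is mildly anti-conservative, so the realised
any-rejection rate of BH under a complete null fluctuates around its
nominal bound across seeds. The Monte-Carlo IC posterior uses
`mc_draws = 10000` by default (posterior probabilities stable to < 0.01
between seeds at 100,000 draws for tables with n ≥ 100); values below
1,000 are accepted with a warning.

## Laboratory screen

The laboratory screen classifies each patient against each catalog-defined
laboratory signal: a signal fires when at least one measurement of the
test, within `window_days = 365` after first exposure start, is strictly
above the upper limit, strictly below the lower limit, or strictly outside
the range, per the signal's direction (a value equal to a limit is
normal). The shipped synthetic catalog has 102 signals over 51 tests,
partitioned 38 above-upper / 39 below-lower / 25 outside-range, mirroring
the structure of laboratory ADR catalogs in the CDM literature (the real
catalog is not public; the fixture is labelled synthetic). The comparator
group is patients on the other catalog drugs, mirroring the registry's
"other drugs" semantics (an all-other-patients option exists). Each
patient-level 2×2 gets an RR and a two-sided Pearson chi-square p-value,
switching to Fisher's exact test when any expected cell is below 5;
significance is RR > 1 and p < 0.05 with no multiplicity adjustment, as is
conventional for this screen. Laboratory evidence *annotates* final
signals; it never gates them. Whether a normal pre-exposure baseline
should be required is left as a configuration extension point.

## Synthetic data: what it emulates, and what it does not

The generators reproduce the statistical skeleton the analysis assumes:

- **Registry** — patients enrol in one stratum on one (brand-named) agent;
  ~3% withdraw consent (initial visit only); the rest contribute
  `n_followups = 3` yearly visits with drug statuses distributed
  (continued 0.6 / switched 0.2 / discontinued 0.15 / other 0.05),
  matching the rough continued fraction seen in biologics registries. ADR
  occurrence is independent per case at `baseline_prob = 0.02` per term,
  multiplied by the embedded risk ratio for signal pairs; embedded events
  are injected only into related/indeterminate reports so the relatedness
  filter is exercisable, and unrelated noise reports are added at 0.005.
  Cohort sizes default to 2,279 RA and 1,940 AS patients.
- **SRS** — reports carry one or two drugs and a Poisson-like number of
  events (mean 1.5); an embedded pair multiplies
  P(event mention | drug on report) by its reporting-rate ratio; 30% of
  drug mentions arrive under brand names.
- **EHR laboratory** — one exposure per patient; measurements uniform in
  the post-exposure window; background abnormality 2% per measurement
  (random side); embedded (drug, signal) pairs hit each exposed patient
  with the stated excursion probability, forced onto the first
  post-exposure measurement in the signal's direction.

All randomness flows from one integer seed through fixed per-module child
seeds, so identical (config, seed) is byte-identical and modules can be
regenerated independently. What the generators deliberately *omit*:
within-patient correlation across follow-ups (the analysis itself counts
follow-ups independently), confounding and channeling bias, time-varying
hazards, duplicate SRS reports, and any MedDRA hierarchy beyond a flat
raw→preferred mapping. Passing tests on these data therefore validate the
*computational pipeline and its statistical calibration*, not robustness to
real-world reporting pathologies.

## The demonstration fixture

The end-to-end fixture is built by direct placement of counts, not
sampling, so its flow shape is a set-arithmetic certainty
(`demo_design()`): per stratum, each designed significant pair receives
a = 12 cases on its drug and c = 4 single occurrences spread over four
other drugs (RR = 21 in RA, 12 in AS; the single occurrences stay below
`min_count`, so no spurious pair is evaluated); noise terms occur at
identical rates everywhere (RR exactly 1). The design yields 51 RA / 36 AS
significant pairs, 16 / 10 label-known, 35 / 26 novel, 13 / 6
SRS-confirmed with 5 confirmed pairs shared between strata, hence 14 final
signals. In the demo SRS, confirmed pairs are given counts far above their
independence expectation and unconfirmed candidates counts *below* it, so
the confirmation split is robust to the seeded Monte Carlo; three
unconfirmed candidates are omitted from the SRS entirely to exercise the
absent-pair annotation. Decoys exercise every filter: unrelated-only
reports, withdrawn patients, and non-continued follow-ups carrying a
would-be signal.

```{r demo, eval = FALSE}
run <- run_pipeline(pv_config(), out_dir = "demo_run")
glance(run)
autoplot(run$signals)
```

## Numerical choices and degenerate inputs

- Ties in the Bayesian FDR ranking are broken by R's stable order;
  the FDR sequence is non-decreasing in rank by construction.
- `relative_risk()` refuses empty margins (a+b = 0 or c+d = 0); empty case
  lists and all-zero tables are hard errors; an empty SRS produces empty
  (not failing) downstream tables and an empty final set.
- The IC Monte Carlo is chunked so memory stays bounded at any `mc_draws`.
- Test problem sizes: calibration and recovery checks run 20 seeded
  replicates at ~21,000 registry cases and 20,000–50,000 SRS reports —
  large enough that binomial standard errors make the assertions sharp,
  small enough to run on a laptop in a couple of minutes.

## Known limitations

Exact-term matching (no MedDRA hierarchy) makes the label exclusion
conservative; the Bayesian IC rule is not frequentist-FDR-calibrated under
a complete null (see above); the laboratory screen has no multiplicity
control by design; and the registry model's independence of follow-ups
within patient understates within-patient clustering that a real cohort
would show. The generators' visit process (fixed yearly visits) is an
assumption, not an inference about any particular registry's sampling
frame.
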