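---
title: "Disproportionality methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Disproportionality methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(faersignal)
```

## The problem

Spontaneous-reporting databases such as FAERS collect adverse-event reports
with no denominator of exposed patients, so incidence cannot be estimated.
What can be estimated is *disproportionality*: whether a drug–event pair is
reported more often than the database's overall reporting pattern would
predict under independence. `faersignal` implements this analysis for one
target drug (the shipped configuration targets trametinib, a MEK1/2
inhibitor used with dabrafenib in BRAF-mutant melanoma) against the rest of
the database.

## Model and statistics

Each analysis unit is a report–term pair: a deduplicated report contributes
one count for every *distinct* preferred term it carries. For term $t$ the
four-grid table is

$$a = \#\{\text{cohort pairs with } t\},\quad
  b = \#\{\text{cohort pairs without } t\},\quad
  c,\ d \text{ likewise for all other reports},\quad N = a+b+c+d.$$

Four measures of the departure from independence are computed per table:

* **ROR** $= ad/bc$, with
  $\mathrm{CI}_{95} = \exp\!\big(\ln \mathrm{ROR} \pm 1.96\sqrt{1/a+1/b+1/c+1/d}\big)$.
* **PRR** $= \dfrac{a/(a+b)}{c/(c+d)}$, with the uncorrected
  $\chi^2 = \dfrac{(ad-bc)^2 N}{(a+b)(c+d)(a+c)(b+d)}$ and a log-normal
  interval with $\mathrm{SE} = \sqrt{1/a - 1/(a+b) + 1/c - 1/(c+d)}$.
* **Information component** $\mathrm{IC} = \log_2 \dfrac{aN}{(a+b)(a+c)}$,
  the base-2 log of observed over expected reporting. Its dispersion uses
  the delta-method variance
  $V(\mathrm{IC}) = (\ln 2)^{-2}\big(1/a - 1/(a+b) - 1/(a+c) + 1/N\big)$
  and the signal bound $\mathrm{IC025} = \mathrm{IC} - 2\sqrt{V}$.
* **EBGM** $= \dfrac{aN}{(a+c)(a+b)}$ — the same observed/expected ratio on
  the natural scale, so $\mathrm{IC} = \log_2 \mathrm{EBGM}$ holds
  identically and is asserted in the test suite to machine precision. The
  interval is log-normal with the all-cells standard error.

Signal criteria: ROR lower bound $>1$ with $a \ge 3$; PRR $\ge 2$ with
$\chi^2 \ge 4$ and $a \ge 3$; IC025 $> 0$; EBGM05 $> 2$. The case-count
gate is read on $a$: the table's own $N$ is in the millions for any real
quarter, so a gate on $N$ would be vacuous.

### What EBGM is (and is not) here

The full MGPS estimator shrinks the observed/expected ratio through a
gamma-Poisson mixture fitted to the whole database. This package computes
the *unshrunken* ratio with a log-normal interval, which is the quantity
printed in many applied signal studies; the consequence is that EBGM and
PRR nearly coincide whenever the cohort is a vanishing fraction of the
database, and the shipped published SOC table indeed shows identical PRR
and EBGM columns at two decimals. Shrinkage is a deliberate non-goal: the
point estimate would no longer satisfy $\mathrm{IC}=\log_2\mathrm{EBGM}$
and the a/b/c/d contract would need the full database layout.

### Numerical choices

* Zero cells leave a statistic `NA` with a `FALSE` flag rather than
  dropping the row; `correction = TRUE` adds 0.5 to every cell of a
  zero-cell table (Haldane–Anscombe). Default off, matching the plain
  formulas.
* $V(\mathrm{IC})$ is clamped at zero: in degenerate tables such as
  $(1,0,0,0)$ the delta expression is negative; the clamp makes the
  degenerate IC interval collapse onto the point value 0.
* A Monte-Carlo alternative (`ic_method = "mc"`) draws cell probabilities
  from a Dirichlet with parameters `counts + 1/2` and takes the empirical
  2.5% quantile of IC. It is the independent cross-check for the
  delta-method bound. The two agree within 0.1 bits across
  reporting-scale tables ($a \ge 10$ with margins an order of magnitude
  larger, the regime of real spontaneous-report tables); for tiny tables
  (all margins comparable to $a$) the posterior is left-skewed and the
  closed form sits up to ~0.2 bits above the simulated quantile, which is
  why the property test draws its tables at reporting scale.
* Report-facing rounding is half-up at 2 decimals (`round()`'s
  half-to-even would disagree with printed percentages such as 45.45).

## Pipeline conventions

* **Dedup key**: FDA receipt date, then case version, then numeric primary
  id. The receipt date is the conventional recency key for quarterly
  releases; a retained record with no parsable date falls back to the
  version ordering and is counted in the run log.
* **Drug matching** is exact (after trim/squish/uppercase) against a
  synonym table, never substring: combination products are enumerated
  explicitly (six expressions for trametinib), so `TRAMETINIBX` does not
  match.
* **Exclusions** are the two mechanical rules that can be operationalised —
  no event term, or no parsable case id — each logged with a reason.
  Vaguer notions of "inconsistent data" are deliberately not implemented.
* **Counting unit**: report–term pairs (default) make $\sum_t a_t$
  well-defined and match event-total bookkeeping; `unit = "report"` is
  available for sensitivity analysis. The choice is recorded in output
  metadata because signal tables are not comparable across units.
* **SOC roll-up** uses one primary SOC per PT, so SOC counts partition PT
  counts; multiaxial membership is resolved in the mapping file, and
  unmapped terms surface as `UNMAPPED`, never merged away.
* **Age** converts `AGE`/`AGE_COD` to years (decades ×10, months ÷12,
  weeks ÷52.18, days ÷365.25, hours ÷8766); values outside [0, 120] years
  become unknown.
* **Onset** requires full Y-M-D precision on both the earliest
  primary-suspect therapy start and the event date; partial dates and
  negative differences (event before therapy) are unknown, the latter
  logged as inconsistent. The onset denominator is the number of cohort
  reports with at least one therapy record — in the published trametinib
  table the onset rows sum to 1589 against 2200 reports, and the package
  reproduces that convention, reporting both denominators in metadata.
  Bins are left-closed and right-open everywhere (`7-28` contains day 7,
  not day 28), the unique convention that partitions without overlap given
  the ambiguous printed labels.
* **Outcome** percentages are per outcome *code*, not per report: a report
  may carry several codes, and the published table's outcome column only
  reconciles under code counting (2789 codes over 2200 reports).

## The synthetic generator

`synthetic_config()` defines a generative model: each report draws one
primary-suspect drug from the drug marginals; a slot count
$K = 1 + \min(\mathrm{Poisson}(\mu - 1),\, k_{\max} - 1)$ (default mean
2.5, max 8); and $K$ PTs with replacement from the drug-specific
distribution $q_{gj} \propto p_j \lambda_{gj}$, collapsed to distinct
terms. The with-replacement-collapse scheme was chosen over weighted
sampling without replacement because its per-report inclusion probability
has a closed form, $\pi_{gj} = E_K[1-(1-q_{gj})^K]$, which makes
`ground_truth()` exact: $E[a] = n(1-p_0)\,p_g\,\pi_{gj}$ and the expected
relative reporting ratio follows from the expected margins. Under
$\lambda \equiv 1$ that expectation is exactly 1 for every pair. Note that
$\lambda$ is a *rate multiplier before renormalisation*: the expected
EBGM of a planted pair is below $\lambda$ (the drug's other terms are
displaced), and parameter-recovery tests compare against the renormalised
expectation, not raw $\lambda$.

Default conditions: 5000 reports over 8 quarters from 2013q2, six
antineoplastic PS drugs (target marginal 0.10), a closed 30-PT/8-SOC
vocabulary with marginals between 0.020 and 0.047 (a deliberate floor — no
ultra-rare terms — so that every drug–PT pair accrues a stable count and
null calibration can be judged at moderate database sizes), three planted
trametinib signals ($\lambda$ 3–4), 25% resubmission rate, 2% eventless
reports, and missingness matched to the published pattern: 13% sex, 24%
age, 14% partial therapy-start dates. Demographics, reporter occupation,
country, route and outcome-code frequencies follow the published
marginals. Resubmissions duplicate a case under the same case id with a
later receipt date and version 2, exercising the dedup rule; the ASCII
writer/reader round-trips the bundles byte-identically.

What the generator does *not* emulate: co-prescription structure (events
are conditionally independent given the PS drug), duplicate cases under
different case ids, reporting trends over time, and real MedDRA coding
noise beyond a configurable raw-term correction map. Passing tests
therefore demonstrate the pipeline's arithmetic and bookkeeping, not
robustness to linkage error or coding drift in real data.

## Scale of the shipped checks

The null-calibration check uses 50,000 reports (about 125,000 report–PT
pairs, 180 drug–PT tables, all with $a \ge 20$) and asserts every
relative reporting ratio within [0.8, 1.25]; observed ranges are ~[0.91,
1.16]. The recovery check plants $\lambda = 5$ on a rare PT sized to ~100
expected pair reports in a 5000-report database and asserts the recovered
EBGM within ±20% of the analytic expectation. The brute-force oracle
enumerates all $6^4$ small tables. These sizes keep the full suite under
a minute while leaving the binomial noise an order of magnitude inside
the asserted bounds.

## Known limitations

* The unshrunken EBGM overstates disproportionality for very sparse pairs
  relative to the shrunken estimator; the $a \ge 3$ gates are the only
  sparsity control.
* `EBGM05` comes from the log-normal interval, not a posterior quantile.
* The delta-method IC025 is anti-conservative by up to ~0.2 bits for
  tables whose margins are comparable to $a$ (see above).
* Onset analysis ignores therapy end dates and rechallenge; only the
  earliest primary-suspect start is used.
* Countries are reported as received (no ISO normalisation), matching how
  published tables print them.
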