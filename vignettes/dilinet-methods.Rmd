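---
title: "Signal detection and mechanism screening for drug-induced liver injury: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Signal detection and mechanism screening for drug-induced liver injury: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dilinet)
```

## The problem

Spontaneous adverse-event reporting systems (FAERS and its peers) collect
unsolicited reports of suspected drug reactions. They have no denominators —
nobody knows how many patients took a drug without incident — so incidence
cannot be estimated. What can be estimated is *disproportionality*: whether a
drug-event pair is reported more often than the rest of the database would
predict. dilinet packages the standard disproportionality workflow for
drug-induced liver injury (DILI) studies of targeted oncology drugs (its
fixtures are modelled on the CDK4/6-inhibitor class: palbociclib, ribociclib,
abemaciclib), together with the downstream mechanism-screening steps — gene-set
intersection, protein-protein interaction (PPI) hubs, pathway
over-representation — and a synthetic report generator that gives every stage
a planted ground truth.

## Reporting odds ratio and the signal rule

For one drug and one event set, reports are cross-classified into the 2x2
table

|            | event         | no event |
|------------|---------------|----------|
| drug       | a             | b        |
| all others | c             | d        |

with counting at *report* level: a report is on the drug margin if any of its
retained primary-suspect assertions names the drug, and on the event margin if
any of its preferred terms (PTs) falls in the queried set. The ANY-match rule
keeps one report from being counted once per member PT of a multi-term query.
The comparator is the whole remaining database, so `a+b+c+d` is the number of
retained reports.

The reporting odds ratio is `ROR = (a*d)/(b*c)` with Woolf (log-scale)
standard error `sqrt(1/a + 1/b + 1/c + 1/d)` and
`CI = exp(log(ROR) ± z * se)`, `z = 1.96` for 95%. Because the interval is
symmetric on the log scale, the point estimate is exactly the geometric mean
of its bounds, and the upper bound equals `ROR^2 / ci_low` — two identities
the test suite exploits to validate the construction against independently
published table rows without access to the underlying database.

A pair is a *positive signal* when it has at least 3 reports and the lower
95% bound exceeds 1. Both halves matter: the count criterion suppresses
unstable signals from tiny cells, the CI criterion controls random
disproportionality. When any cell is zero the Haldane–Anscombe correction
adds 0.5 to all four cells before estimation; the raw `a` is always kept as
the report count so the correction cannot manufacture an `n >= 3`.

Scans across a grid of terms are reported **unadjusted** for multiplicity, as
is conventional for pharmacovigilance screens (they generate hypotheses, not
confirmations); the scan output carries a `multiplicity_adjusted = FALSE`
flag so downstream consumers cannot mistake this.

## Dictionary hierarchy

Events are organised as PT → HLT (high-level term) → SMQ (standardised
query), with SMQ membership many-to-many over PTs and a *comprehensive* SMQ
expanding through child SMQs by set union. Queries expand at any of the three
levels; SMQ members carry a narrow/broad scope and expansion defaults to
`combined` (both scopes), the maximal-sensitivity reading appropriate for a
comprehensive liver-disorder search, with `narrow` available behind a flag.
Real MedDRA files are licensed, so the package defines its own plain-CSV
dialect with the same structure; codes are opaque, case-sensitive
identifiers and names are labels only (the real hierarchy contains distinct
SMQs sharing a display name, so names cannot key anything).

## Deduplication

Cases accumulate follow-up versions, and counting more than one version of a
case inflates every cell. The retained-version rule is: keep the rows of the
highest `case_version` per `case_id`, breaking ties by latest receipt date,
then by lexicographically greatest `report_id`. The rule is deterministic and
idempotent, and the output carries provenance counters (rows read / dropped /
retained) that must sum exactly — both properties are asserted on fuzzed
tables. Cases reporting several study drugs are surfaced as a diagnostic but
retained; removing them would bias the comparator.

## Descriptive summaries

Cohort tables report counts and percentages (half-up rounding, the convention
of printed pharmacovigilance tables — base R's banker's rounding would
disagree with any published table in half the edge cases). Time-to-onset is
`event_onset_date - therapy_start_date` in whole days; quartiles are Tukey
hinges (`stats::fivenum`): the published tables this format mirrors do not
state their quartile convention, so one is fixed and documented. Negative
onsets are excluded into the missing count rather than clamped — a negative
interval is a data-quality failure, not a zero.

## The synthetic report generator

The generator is the package's ground truth, not a fixture dump. Its model:

* **Exposure.** Each case is exposed to each drug independently with its
  configured probability; a case with no exposure is assigned one drug
  (weighted by exposure probability), since a spontaneous report without a
  drug does not exist. With configurable probability a case receives one
  extra drug, exercising multi-drug cases.
* **Events.** Each monitored PT occurs with odds equal to its baseline odds
  times the product of planted multipliers `omega` over exposed drugs. This
  logistic-odds form makes the odds ratio the exact estimand: a planted
  `omega = 4` *is* an asymptotic ROR of 4 against an unexposed comparator,
  which the tests confirm with an independent million-case simulation of the
  same structural model.
* **Background events.** Every report additionally carries one filler PT from
  a background pool. Without it, cases with no monitored event would vanish
  from the database and the `b`/`d` margins would be degenerate; with it, the
  event margin of any monitored query is untouched.
* **Primary suspect.** One exposed drug per case is the PS assertion; others
  are secondary/concomitant. The choice is weighted by each exposed drug's
  planted odds contribution to the events that actually occurred — reporters
  name the drug they suspect, and suspicion tracks the likely culprit — and
  is uniform when nothing distinguishes the exposed drugs. A uniform choice
  would misclassify multi-exposed cases into the comparator arm with
  elevated event odds and attenuate the estimated ROR below the planted
  value; the suspicion weighting keeps the PS-restricted ROR an (almost)
  unbiased estimator of `omega`, with only the residual contamination from
  non-event multi-drug cases.
* **Versions, demographics, dates.** A configured fraction of cases is
  re-emitted as version-2 follow-ups (exactly `floor(f*n)` cases, so tests
  can assert counts). Sex skews female (the fixture emulates a breast-cancer
  drug class), ages are truncated normal around 60, outcomes and reporter
  types come from fixed categorical menus, and all three missingness
  fractions are configurable. Onset days are log-normal with per-drug
  configured median (sdlog = 1, right-skewed as real time-to-onset data are);
  therapy start never follows event onset by construction.
* **Determinism.** One seeded RNG stream consumed in a fixed vectorised draw
  order; identical config + seed gives byte-identical files, asserted at the
  file level. The global RNG state is saved and restored around every
  simulation.

What the generator does **not** emulate: reporting dynamics over time
(stimulated reporting, the Weber effect), free-text drug names and
misspellings, real MedDRA coding practice, correlated event co-reporting, or
duplicate reports that differ in content between versions. Passing
calibration therefore shows the statistics are computed correctly under a
clean generative model — not that the pipeline is robust to every FAERS
pathology.

## Calibration scenarios and problem sizes

Two fixed scenarios (`calibration_config()`) calibrate the signal rule; their
parameters are package conventions chosen once:

* **Null:** two drugs at 10% exposure, one event at 2% baseline, no planted
  association, 2,000 cases; over 500 replicates the signal rule must fire for
  the monitored pair in at most 7% (nominal one-sided 2.5% plus the slack the
  discrete count criterion introduces).
* **Planted:** the same database with `omega = 4` on one pair and 5,000
  cases; over 200 replicates the 95% CI must cover 4 at least 90% of the
  time and the median estimate must land in [3.2, 5.0] (the attenuation band
  discussed above).

These replicate counts keep the whole calibration under two minutes while
leaving the binomial noise on the asserted rates well inside the asserted
margins.

## Network and enrichment conventions

* Gene symbols are trimmed, uppercased, optionally alias-mapped, and
  deduplicated; intersection is plain set intersection (commutative, bounded
  by its inputs — asserted, since the published intersection sizes this
  mirrors are database-version-dependent and not reproducible).
* PPI edge lists accept scores on either the 0–1 scale or STRING's 0–1000
  integer export scale, auto-detected from the maximum (a file whose scores
  all happen to lie in [0,1] on the integer scale is indistinguishable, so
  the detection is overridable). The default threshold 0.7 is the
  high-confidence STRING convention. The network is undirected; reversed and
  duplicate edges collapse to the maximum score; self-loops drop.
* Hub ranking is by node degree, descending, ties alphabetical — degree is
  the one topology metric the mirrored analyses actually use; other
  centralities are out of scope. Isolated genes are excluded from ranking by
  default (degree 0 carries no centrality signal) but can be kept in exports.
* Over-representation uses the upper-tail hypergeometric test (one-sided:
  only enrichment is of interest), with the universe defaulting to the union
  of pathway members — the most reproducible convention when the true assay
  background is unknown — and configurable to an explicit list.
  Benjamini–Hochberg adjustment runs across all tested pathways before
  top-`k` truncation, so truncation cannot distort the FDR. Pathway-size
  filters default to off (`min_set = 1`, `max_set = Inf`).

## Numerical choices

* Haldane–Anscombe 0.5 on all four cells, only when a zero cell exists;
  `corrected` is flagged in every output.
* Degenerate margins (drug or comparator entirely absent) raise a classed
  error; scans catch it per pair and emit NA statistics rather than abort.
* Display rounding is half-up to 2 decimals, always alongside full-precision
  values, never in place of them.
* Sorting tie-breaks are stated everywhere a sort appears (dedup retention,
  hub ties, enrichment ties) so identical inputs give identical files; the
  pipeline manifest records an MD5 checksum per output to make determinism
  checkable from outside.

## Limitations

Disproportionality cannot demonstrate causality or quantify risk; it ranks
hypotheses. The package deliberately implements only the ROR among
disproportionality statistics (no PRR, no Bayesian shrinkage estimators), no
record linkage beyond exact case identity, and no live database access — all
external resources (report extracts, dictionaries, gene and pathway
collections, PPI exports) are consumed as local files in documented
plain-text dialects.
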