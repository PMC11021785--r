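# dilinet

Pharmacovigilance signal detection and drug–gene network analysis for
drug-induced liver injury (DILI), as a tested, reusable R pipeline.

Spontaneous adverse-event databases (FAERS-style) record suspected drug
reactions without denominators, so risk is screened by *disproportionality*:
is a drug–event pair reported more often than the rest of the database
predicts? dilinet implements the standard workflow around the reporting odds
ratio for liver-injury studies of oncology drug classes (its fixtures emulate
the CDK4/6 inhibitors palbociclib, ribociclib and abemaciclib), plus the
mechanism-screening steps that typically follow a positive signal. It is
aimed at pharmacoepidemiologists and methods developers who need every stage
of that workflow testable offline.

For one drug and one event set, reports are cross-classified into a 2×2
table — `a` (drug & event), `b` (drug, other events), `c` (other drugs,
event), `d` (neither), with the whole remaining database as comparator — and

```
ROR    = (a·d) / (b·c)
se_log = √(1/a + 1/b + 1/c + 1/d)          (Woolf)
95% CI = exp( ln ROR ± 1.96 · se_log )
```

A pair is a **positive signal** when `a ≥ 3` and the lower CI bound exceeds 1.
Zero cells take the Haldane–Anscombe 0.5 correction; `a` stays raw for the
count criterion. Around this core the package provides:

* **PT → HLT → SMQ dictionary** querying (plain-CSV dialect; narrow/combined
  scope; comprehensive SMQs expand through children by set union);
* **report store**: validated CSV reading, drug-name normalisation with
  synonym tables, primary-suspect filtering, and deterministic case-level
  deduplication (highest version, then latest receipt date, then report id);
* **descriptive tables**: cohort breakdowns with half-up percentages and
  Tukey-hinge time-to-onset quartiles;
* **gene networks**: gene-list normalisation, target × disease set
  intersection, STRING-style PPI edges thresholded at 0.7 combined score,
  degree-ranked hubs;
* **enrichment**: upper-tail hypergeometric over-representation against GMT
  collections with Benjamini–Hochberg adjustment;
* **synthetic generator**: FAERS-like databases with planted odds
  multipliers, duplicate case versions, configurable missingness and onset
  structure — the ground truth every stage is tested against;
* **pipeline**: one-config end-to-end run with a checksummed manifest, and a
  `dilinet` CLI (`inst/scripts/dilinet`) over the same functions.

## Worked example

Simulate a database with a planted odds multiplier of 4 on one drug–event
pair, deduplicate, and test that pair:

```r
library(dilinet)

cfg <- sim_config(
  n_cases = 5000,
  drugs = c(drugA = 0.1, drugB = 0.1),
  events = c(PT001 = 0.02),
  planted_or = data.frame(drug = "drugA", pt_code = "PT001", omega = 4),
  seed = 7)

sim   <- simulate_database(cfg)
clean <- deduplicate(sim$reports)
clean
#> <clean_report_set> 5368 rows retained (5898 read, 530 dropped as superseded versions); 5000 cases

tab <- build_contingency(clean, "drugA", "PT001")
tab
#> <contingency_table> a=168 b=2356 c=53 d=2423 (N=5000)

s <- compute_ror(tab)
s
#> <signal_stats> ROR 3.26 (95% CI 2.38-4.46), N=168
detect_signal(s)
#> [1] TRUE
```

Reading the output: superseded case versions are discarded before counting;
the reports carrying both the drug and the event form cell `a`; the
estimated ROR is statistically compatible with the planted 4 (its 95% CI
covers it), and the pair fires the signal rule.

`make_fixture_bundle()` writes a complete miniature study (reports,
dictionary, gene lists, PPI edges, pathways) and `run_pipeline()` executes
all stages against it; see `vignettes/dilinet-methods.Rmd` for the model,
conventions and their rationale.

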