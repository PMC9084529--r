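---
title: "Methods: registry harmonization, deduplication, and registration-quality scoring"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: registry harmonization, deduplication, and registration-quality scoring}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ctrquality)
```

This vignette documents the models and procedures the package implements,
the choices made where the design was genuinely open, and what the synthetic
study conditions do and do not demonstrate about real registry data.

## The problem and the data model

Clinical trial registries overlap: a trial recruiting in Germany may be
registered on ClinicalTrials.gov, on the DRKS, and appear again through the
WHO ICTRP meta-registry, sometimes with diverging titles, dates and sample
sizes. Any registry-level statistic — pre-registration rates, registration
quality, publication rates — is biased unless records are first harmonized
into one schema and deduplicated into trials.

The harmonized record model carries: primary and secondary IDs, source
registry, title, registration and start dates *with their precision*, study
type (mapped through a documented synonym table), sample size, sponsor
names, contact e-mails and recruiting countries. Multi-valued fields are
";"-joined text so that the interchange CSV and the line-delimited JSON form
round-trip identically.

### Date precision

Registry exports mix full dates, month-only dates and bare years. Month
precision floors to the first of the month and year precision to January 1,
and the precision is stored alongside the date. The alternative — imputing
mid-month or mid-year — would silently convert registration ties into
pre- or retro-registrations. With flooring plus the coarser-precision
comparison rule (below), coarse dates err on the side of calling a trial
pre-registered, which is the conservative direction for a quality audit
that wants to avoid accusing trials of late registration.

## Deduplication

The step-wise process mirrors how registry crosswalks are actually built:

1. **ID cascade.** Pairs sharing a primary ID, or where one record's primary
   ID appears among another's secondary IDs (case-insensitive,
   whitespace-stripped), are linked unconditionally. ID evidence is never
   overruled by the classifier.
2. **Blocking.** Classifier candidates are restricted to pairs agreeing on
   the first title token with registration years at most one apart, unioned
   with pairs sharing a contact e-mail. Blocks larger than 50 records are
   skipped (first tokens like "study" carry no signal). Blocking trades a
   measurable miss rate for tractability; the tests measure its completeness
   against planted ground truth (≥ 95% of planted pairs on the default
   scenario) rather than assuming it.
3. **Pairwise classifier.** A probability random forest (ranger, 300 trees,
   seeded) over six features: shared-ID flag, token-set title similarity,
   registration- and start-date gaps in days, min/max sample-size ratio, and
   shared contact. Missing feature values are encoded as −1 with explicit
   missingness indicators, letting trees split on "gap unknown" separately
   from "gap large". The default decision threshold is 0.5 and exposed;
   sweeping it can only shrink the edge set (tested as a monotonicity
   property).
4. **Clustering and merging.** Union of ID and classifier edges, connected
   components, one unified trial per component. Transitive conflicts
   (A≈B, B≈C, A≉C) resolve by accepting the chain — the simplest policy,
   and with blocking plus a 0.5 threshold the giant-component failure mode
   did not occur in any tested scenario. Merged trials take the earliest
   registration date and earliest non-missing start date (with the
   precision of the record that supplied them); conflicting non-date fields
   prefer the ClinicalTrials.gov member, then DRKS, then ICTRP partners,
   tie-broken by lexicographic record ID. The trial ID is the
   lexicographically smallest member ID, making cluster identity
   deterministic.

Title similarity is a token-set measure: case- and diacritic-folded,
punctuation-stripped titles are reduced to sorted unique token strings and
compared by normalized Levenshtein distance. This is robust to word-order
changes and small edits, the two perturbations registry mirrors actually
introduce.

## Per-trial classification

**Pre-registration.** A trial is `pre` iff registration date ≤ start date,
compared after flooring both dates to the coarser of their two precisions;
equality counts as pre-registered (registration "by study start"). Missing
either date gives `unknown`, which models exclude. Monotonicity (delaying
registration can flip pre→retro but never retro→pre) is a tested property.

**Structural factors.** The shipped context table lists German Universities
of Excellence with funding windows and KKS sites with opening years, as
diacritic-folded regular expressions matched against sponsor names. Window
boundaries are inclusive on both ends; `uoe_active` compares the *start
date* against the funding window (the choice between start and registration
date was open; start date is the moment the structural support could have
acted on trial conduct, and both remain expressible by editing the context
or the input columns). City patterns use word boundaries and lookahead
exclusions for ambiguous names (e.g. "Frankfurt" vs "Frankfurt (Oder)").
`university_sponsor` is the substring "universit", which captures German
and English university and university-hospital names. The KKS flag is a
location proxy — a trial a KKS *could* have supported — not evidence of
cooperation; treating it as exposure would be an ecological fallacy, which
is why the package only ever reports it as a flag.

## Sampling

Study types that cannot be rated as standalone trials (post-marketing,
expanded-access, diagnostic-test, other) are excluded first, with a
per-reason tally satisfying input = remaining + excluded at every stage.
The manual-inspection sample is stratified (default: start year × UoE ×
KKS) with proportional allocation and largest-remainder rounding — the
stratification variables were given, the allocation method was an open
choice; largest remainder keeps every stratum within one trial of exact
proportionality, which the tests assert. Empty strata are skipped and their
share redistributed. Manual exclusion labels (extension, multi-part,
patient-registry, follow-up, sub-study trials) are a judgment input, never
derived from record text.

## The quality rubric

Eight categories were identified for rating registration quality: basic
study data (title), study design, outcomes, interventions, analyses,
funding, contact details and result data. Rated criteria exist for title,
design, sample size, masking, inclusion criteria, primary/secondary outcome
and intervention; funding, contact details and result data are represented
in the codebook but carry no rated criteria (contacts feed a survey,
results feed the article search). The scoring rules:

* **Title (0–1):** intervention (waived for observational studies),
  indication and outcome all present, and the titled outcome is a primary
  outcome. Only one point exists, so a title that both lacks specificity
  and names a non-primary outcome still scores 0, not −1.
* **Design (0–1):** adequate and internally consistent.
* **Sample size (0–1):** present or not.
* **Masking (0–2):** description of who is blinded ("double blind"
  suffices) earns 1; naming the responsible party as well earns 2. Not
  applicable for observational and open-label trials.
* **Inclusion criteria (0–2):** 0 if screening criteria are unclear, 2 if
  diagnoses *and* accompanying measures are given for all key criteria,
  else 1.
* **Outcomes (0–5 each for the rated primary and secondary):** one point
  each for outcome type, named measure, time frame, metric and aggregation
  method; survival outcomes are not penalized for a missing aggregation
  method (Kaplan–Meier is the standard), and the metric point is granted
  when inferable or moot. Only the most detailed outcome per role is rated,
  and secondary outcomes highly similar to a primary are skipped where
  possible ("highly similar" is an annotation flag, not a computed
  similarity — the judgment is the rater's).
* **Intervention (0–2):** active ingredient or intervention type earns 1,
  dosage or detailed description earns 2. Not applicable for observational
  studies; control arms are not rated.

The rubric consumes structured annotations, not free text: the original
rating act is human judgment, and automating text→flags would be a
different (NLP) contribution. The annotation codebook ships at
`inst/extdata/annotation_codebook.csv`; published example entries with
their ratings ship as the canonical fixture set under
`inst/extdata/worked_examples/` and are asserted exactly in the tests.

**Aggregation.** The aggregate score is the unweighted mean over applicable
categories of points/attainable points ("over all criteria" reads as equal
category weight). The alternative — total points over total attainable —
weights outcome categories 5× and is available via
`aggregate_quality(..., method = "points_ratio")` because the wording is
genuinely ambiguous. Not-applicable categories leave the denominator.

## Regression models

Logistic regression for the binary outcomes (pre-registration, article
availability; coefficients reported as odds ratios with Wald 95% intervals)
and linear regression for the aggregate quality fraction. Registration year
and sample size are standardized by subtracting the mean and dividing by
twice the standard deviation, putting their coefficients on the scale of a
binary predictor's. Four canonical variants (`model_battery()`): UoE alone,
UoE + covariates, and the same pair for KKS. For pre-registration the data
are filtered to registration dates after 2008 — implemented as ≥ 2009-01-01
and configurable — because the DRKS only came into existence that year and
earlier years cannot carry DRKS membership effects. Missing data are handled
complete-case per model with dropped-row counts reported in `glance()`;
perfect separation is detected (fitted probabilities at the 0/1 boundary)
and flagged rather than silently accepted. Per-criterion time trends are
simple linear regressions of the yearly mean score on the start year, per
registry group, skipping group×criterion cells with fewer than three
distinct years.

## The synthetic study conditions

The generator's defaults are fixed study conditions, not tuning knobs. They
emulate the German registry landscape: 24.3% observational trials, home
registries drawn as ClinicalTrials.gov 0.55 / DRKS 0.25 / EUCTR 0.12 /
ISRCTN 0.08 with a 30% cross-registration rate (giving roughly 62% / 29%
membership), 45% university sponsors, 7.5% UoE and 27% KKS draws with 6%
jointly, registration years 2005–2020, an 8% internal-ICTRP duplicate rate,
and planted models whose coefficients carry the signs and approximate
magnitudes of the real-data phenomena: lower pre-registration odds for
observational trials (log-odds −0.8), UoE (−0.75), KKS (−0.32) and DRKS
(−0.4); a positive quality trend of 0.009/year with observational −0.10,
ClinicalTrials.gov +0.08 and residual SD 0.11; an article-availability
baseline near 43%. Duplicates share secondary IDs with probability 0.7,
otherwise they are only fuzzy-linkable through titles perturbed at an 8%
per-word edit rate, dates jittered ±3 days, and contacts shared 85% of the
time. The default scenario is 2,000 trials — sized so a full
generate–link–classify–score–fit loop runs in seconds on a laptop; the
parameter-recovery studies use 5,000-trial tables over 20 seeds and the
type-I study 500 replicates of 400 trials, sizes at which Wald coverage and
rejection rates are tight enough to be diagnostic.

Quality annotations are generated by computing a per-trial latent target
fraction (baseline + trend + effects + Gaussian noise, clamped to [0, 1])
and then allocating integer category points whose mean fraction matches the
target as closely as the grid allows — a small dynamic program over the
tenths grid the category maxima induce. All randomness therefore lives in
the latent noise term: with zero noise and no effects every scored
aggregate equals the baseline exactly, which pins the scoring chain down in
tests. The trial-level shortcut `simulate_trial_table()` leaves the quality
outcome on the latent (unclamped) scale and is the generator used for
parameter-recovery and type-I studies, where clamping would bias
coefficients near the boundary.

What passing tests on these conditions show: the linkage machinery recovers
planted duplicate structure (pairwise F1 ≥ 0.9), the regression layer has
nominal coverage and size, the rubric engine is exactly the stated truth
table, and every stage conserves rows. What they do not show: performance
on real registry free text (eligibility prose, outcome prose are not
emulated), real-world ID quality, actual KKS cooperation, or the real-data
counts and coefficients — those require the registry snapshots themselves.

## Numerical and degenerate-input choices

Ties in outcome selection break by annotation order; ties in merge conflicts
by registry preference then lexicographic ID; largest-remainder ties by
stratum order. Constant inputs to the 2-SD standardizer are an error (zero
SD), not a silent NaN. Empty candidate sets, empty files with valid headers,
and trials missing all dates flow through as empty tibbles, `unknown`
classifications, or flagged warnings rather than failures. Percentages are
kept at full precision internally and rounded half-up to two decimals only
for display, because half-to-even banker's rounding (R's default) disagrees
with how such tables are conventionally printed.

## Known limitations

The AACT reader consumes a flat single-file export; real AACT snapshots
split sponsors and contacts into relational tables, which users can
pre-join before ingestion (the YAML mapping then needs no change). The
matcher is only as good as its training pairs; `train_matcher_from_sim()`
trains on synthetic scenarios, and transferring it to real exports would
require labeled real pairs. The structural context table is a curated,
editable snapshot of funding windows and opening years, not an
authoritative registry of them.
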