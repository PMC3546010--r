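---
title: "Rule-based classification of positive blood cultures into episodes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Rule-based classification of positive blood cultures into episodes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bcepisodes)
```

## The problem

A positive blood culture is a single laboratory observation — one database
row — of a microorganism grown from a blood specimen. For surveillance and
outcome research these rows must be aggregated into *episodes* and each
episode answered four questions: Was it a contamination by skin flora or a
true bloodstream infection (BSI)? Was the infection monomicrobial or
polymicrobial? Did it begin in the community or in hospital? And if in the
community, was it healthcare-associated (preceded by recent hospital
contact)?

Clinical microbiologists answer these questions routinely, but their
assessments are rarely recorded in a reusable form. `bcepisodes` implements
deterministic computer algorithms that answer them from two administrative
sources alone — the laboratory database and a hospital-contact registry —
and provides the machinery to evaluate those algorithms against recorded
physician assessments with 2×2 agreement tables, percent agreement, Cohen's
kappa, and crude 30-day-mortality contrasts.

## The data model

Four flat tables, all keyed by an opaque `patient_id` and carrying calendar
dates only (registries record no clock times, so all arithmetic is in whole
days):

* **blood cultures** — `record_id`, `draw_date` (optional), `receipt_date`
  (never missing), `organism_name`, `source_site`. Laboratories number
  positive cultures per bottle (or per bottle pair), so one specimen can
  yield several duplicate rows of the same organism.
* **hospital contacts** — inpatient admissions and outpatient
  (ambulatory/emergency-room) visits with `indate`/`outdate`.
* **physician assessments** — two variables per assessed culture date: one
  places the culture on the contamination / community-onset /
  healthcare-associated / hospital-onset axis, the other on the
  contamination / monomicrobial / polymicrobial axis. The two must agree on
  whether the culture was a contamination; disagreement is a validation
  error.
* **follow-up** — date of death and emigration, plus a precomputed
  comorbidity category (`0`, `1-2`, `>2`); comorbidity scoring itself is out
  of scope here.

Every analysis date is the **best-estimate-date**: the draw date, or the
receipt date when the draw date was not recorded (roughly 9% of rows in
routine extracts; the receipt date is never missing).

## Episode derivation

**Computer episodes** are purely algorithmic: a patient's first episode
comprises all positive cultures on the earliest best-estimate-date and the
day after; the next episode starts at the first available date after that
2-day span, and so on. The episodes partition the records, and appending a
later culture never disturbs earlier episodes.

**Reference episodes** are anchored by physician assessments: the earliest
assessed best-estimate-date opens the first reference episode, the next
assessed date after it the second, iterated to exhaustion. Unassessed
cultures within 30 days *after* an anchor are attached to that episode.
Three situations are not fully determined by that description, and the
package resolves them as follows:

* an unassessed culture covered by two anchors' 30-day windows joins the
  *earliest* one; an assessed culture always joins the episode of its own
  assessed date, which takes precedence over any attachment window;
* an unassessed culture that precedes the patient's first assessed date
  belongs to no reference episode (it still forms a computer episode);
* several assessments on one date keep the first by file order, with a
  warning.

A patient's first reference episode is **incident** when no positive
culture exists in the 365 days before its index date; the boundary is
inclusive (a culture exactly 365 days earlier blocks incidence), matching
the reading of "within 365 days" as days 1–365. Cultures from a lag period
before the study window participate in this check only.

## The four classification rules

**Contamination.** An episode is a contamination when common skin
commensals, and nothing else, grew — and only on the episode's earliest
date within a 5-day period (a repeat-growth screen: the index date plus the
four following days, evaluated against *all* the patient's cultures, since
repeat commensal growth anywhere in that window is evidence of true
infection). The commensal list is an explicit, overridable lexicon:
coagulase-negative staphylococci (as a species list — coagulase status is
not derivable from the genus name), *Propionibacterium*, *Bacillus*,
*Micrococcus* and *Corynebacterium* as genus-level prefixes, and the
provisional labels "coagulase-negative staphylococcus" and "coryneform
rod". Everything unmatched is a pathogen. Matching is case-insensitive
after whitespace normalisation; no other name normalisation is attempted,
because the rule operates on recorded labels.

One consequence worth stating plainly: the rule is *not* monotone in the
lexicon. Moving an organism from pathogen to commensal usually moves
episodes toward contamination, but it can also do the reverse — an
all-commensal episode whose 5-day window contains a culture of the moved
organism acquires new repeat-commensal evidence and flips to BSI. The test
suite asserts the monotone parts (the organism classification itself, the
pathogen clause, single-date patients) and verifies that every
contamination-to-BSI flip is attributable to newly-commensal window growth.

**Polymicrobial.** A BSI episode with two or more distinct recorded
organism types. Duplicate per-bottle rows collapse; a provisional label
counts as its own type, so *Candida albicans* plus "yeast-like organism" is
polymicrobial — a known over-call inherited from incomplete speciation.

**Place of onset.** For every combination of a member best-estimate-date
and an inpatient contact, `time_in = date − indate` and
`time_out = date − outdate`; pairs with `time_in < −2` or `time_out > 30`
are discarded. If the lowest retained `time_in` is ≥ 2 days the episode is
hospital-onset. If it is 0 or 1 (admitted the day of or before the
culture), the episode is still hospital-onset when a transfer pattern shows
arrival from another ward: a retained contact ending on the culture date
(`time_out = 0`) after a stay of ≥ 2 days (lowest `time_in` 0) or ≥ 1 day
(lowest `time_in` 1), or a retained contact spanning the culture date from
an earlier admission (`time_in > 1`, `time_out < 0`). Otherwise it is
community-onset.

Two interpretation choices here are deliberate and documented:

* the transfer stay-length condition is sometimes written as
  "`time_out − time_in` ≥ 2 days", which is algebraically impossible for a
  single contact (it equals `indate − outdate` ≤ 0); the package implements
  the magnitude of that difference, i.e. stay length `outdate − indate`;
* an episode with *no* retained inpatient contact is classified
  community-onset with a warning. In the source setting all cultures were
  hospital-drawn, so the case signals unusual input rather than a defined
  rule branch.

**Healthcare association.** A community-onset episode is
healthcare-associated when any retained inpatient *or* outpatient pair
shows a contact that ended 1–30 days before the culture:
`(time_in ≤ 30 and time_out > 0)` or
`(time_in > 30 and 30 ≥ time_out > 0)`.

## Concordance evaluation

Reference episodes are the analytical unit. Each is paired with the
computer episode whose index date matches, falling back to the computer
episode whose 2-day window contains the reference index date (how pairing
was done in the source setting is not recorded; this is the package's
choice, and disjointness of computer windows makes it unambiguous). Four
2×2 tables are then built, rows = algorithm, columns = physician:
contamination-vs-BSI over all pairs; mono-vs-polymicrobial and
community-vs-hospital over pairs both sides call BSI; healthcare
association over pairs both sides additionally call community-onset.

For each table the package reports percent agreement `(a+d)/n` and Cohen's
kappa

$$\kappa = \frac{P_o - P_e}{1 - P_e}, \qquad
  P_o = \frac{a+d}{n}, \qquad
  P_e = \frac{(a+b)(a+c) + (c+d)(b+d)}{n^2},$$

with the Landis–Koch verbal bands (slight ≤ 0.2 < fair ≤ 0.4 < moderate
≤ 0.6 < substantial ≤ 0.8 < almost perfect ≤ 1; the conventional band
edges overlap in print, so shared boundaries go to the lower band, and
negative values are "poor"). Kappa is reported to 2 decimals and
percentages to 1 decimal in printed summaries, matching surveillance
reporting practice.

30-day mortality (death on days 0–30 after the index date, day 30
inclusive) is contrasted across the four cells of each table as crude odds
ratios against the concordant cell presumed prognostically worst
(both-BSI, both-polymicrobial, both-hospital-onset,
both-healthcare-associated). With a single binary covariate the logistic
model has a closed form, so the OR is computed exactly as
`(d₁s₀)/(d₀s₁)` with the usual log-normal 95% CI; the tests cross-check
this against `glm()`. Episodes of patients who emigrated before day 30
without a recorded death are excluded from the denominators and reported
separately. Zero cells raise an error rather than being silently
continuity-corrected.

```{r counts-example}
evaluate_from_counts(7288, 276, 240, 1678, "contamination_vs_bsi")[c("percent_agreement", "kappa", "band")]
```

## The synthetic registry generator

No public registry of this shape exists, so the package ships a generator
whose output is a *construction*, not a simulation fit: every planted
episode's cultures and contacts are built so that the rules above provably
yield the planted class. That makes ground truth exact by design and turns
the full pipeline into a testable object.

What it emulates: per-bottle duplicate rows (1–4 per organism and date at
a site numbering per bottle, 1–2 at a site numbering per bottle pair);
missing draw dates at rate 0.088; commensal and pathogen organism mixes
including provisional labels; admissions, same-day transfers, wards
spanning the culture date, and prior contacts 1–30 days before a culture;
physician assessments covering 90% of episodes whose labels equal the
truth except for independent per-comparison flips; 30-day deaths at
class-dependent rates; occasional lag-period cultures and emigrations.

Construction details that keep the ground truth exact:

* episodes of one patient are spaced ≥ 75 days apart, so contamination
  windows, 30-day attachment windows and 30-day contact filters of
  consecutive episodes cannot interact;
* missing draw dates are injected only on rows whose receipt date equals
  the draw date, so blanking the draw date never moves a
  best-estimate-date (the price is a mild correlation between missingness
  and zero receipt lag, which none of the rules consume);
* a community episode spanning two culture dates is admitted on the index
  date, never the day before — otherwise the day-2 culture would pair with
  the admission at `time_in = 2, time_out < 0` and legitimately trip the
  spanning-transfer clause.

Default rates are fixed once and loosely calibrated to the shape of a
large two-hospital cohort: 20% contamination, 10% polymicrobial among
BSI, 25% hospital onset, 15% healthcare association among community
onset, flip rates 0.03 / 0.05 / 0.17 / 0.36 for the contamination,
microbial, onset and HCA comparisons (echoing the observed pattern that
place-of-onset and especially HCA judgements disagree far more often than
the contamination call), and 30-day death probabilities of 0.10 / 0.20 /
0.30 for contamination, community-onset and hospital-onset episodes
(overall mortality near 21%).

What it does **not** emulate — and therefore what passing tests do and do
not show: no microbial epidemiology or seasonality, no antibiotic
resistance, no site-clustered missingness (treated as independent per
record), no assessment timing drift, and no ambiguity about which bottles
form a culture set (real laboratory numbering does not allow
reconstructing sets; the generator does not pretend otherwise). Perfect
recovery on synthetic cohorts demonstrates that the implementation applies
the rules exactly as specified; it says nothing about how well the rules
themselves approximate clinical judgement on real data, which is precisely
the question the concordance module quantifies when real assessments are
available.

## Numerical and validation choices

* All window constants are configurable and default to: 2-day episode
  span, 5-day contamination window, 30-day HCA window, 30-day reference
  attachment window, 365-day incident lookback. All are positive-integer
  day counts.
* CSV validation is total: every row is either accepted or enumerated once
  in a validation report with its file line number; files are cleaned in
  one pass rather than failing on the first error, matching registry
  practice. A missing required column aborts (schema error).
* Episode tables round-trip losslessly through CSV, with a single `NA`
  sentinel for labels that do not apply to an episode's kind (a
  contamination episode has no onset and no HCA flag by definition).
* The test suite checks the episode builder against an independent
  day-scan oracle and the onset/contamination/HCA rules against
  brute-force raw-pair enumerations on 1,000 random patients with up to 5
  contacts each; kappa is cross-checked against an independent
  implementation and the crude OR against a logistic fit. Planted-truth
  recovery is verified on cohorts of about 2,000 episodes (1,850
  patients), a size chosen to make binomial checks on a 5% flip rate
  sharp at three standard errors while keeping the suite quick.

## Known limitations

* The physician labels in the evaluation design are a reference, not a
  gold standard; agreement statistics quantify concordance, not accuracy.
* The commensal lexicon is a name-matching device; it cannot rescue
  misrecorded or unspeciated organisms, and provisional labels inflate the
  polymicrobial count by design.
* Onset classification presumes hospital-drawn cultures; records without
  any retained inpatient contact fall back to community with a warning.
* The adjusted (age/sex/comorbidity) mortality models, Kaplan–Meier
  curves and descriptive cohort comparisons that usually accompany this
  kind of evaluation are deliberately left to standard statistical tools;
  the package stops at the crude closed-form contrasts.
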