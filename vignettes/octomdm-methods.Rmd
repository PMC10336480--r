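---
title: "Methods: rule-based MDM decision support and agreement measurement"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: rule-based MDM decision support and agreement measurement}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(octomdm)
```

## The problem and the model

Multidisciplinary team meetings (MDMs, tumor boards) decide cancer
treatment plans collectively, but meeting time does not scale with caseload.
`octomdm` implements a semiautomatic triage procedure for upper
aerodigestive tract cancers: encode the case file a tumor board actually
uses, generate a guideline-backed therapeutic proposal automatically for
routine cases, and reserve in-person discussion for the cases that need it.
The procedure has three layers:

1. **Case model.** A case is (sublocation, TNM stage, histology,
   per-modality feasibility, relapse, poor-prognosis factors). All
   vocabularies are closed enumerations; anything outside them is rejected
   at validation time, because a decision rule applied to a mistyped case is
   worse than no decision.
2. **Decision engine.** A rule table maps (sublocation, stage class) to
   candidate regimens; feasibility filtering removes regimens containing an
   infeasible modality; relapse, metastasis or an emptied option set
   escalate the case to a face-to-face MDM.
3. **Consensus workflow.** The engine proposes; the five consultant roles
   dispose. A review is validated only by a unanimous vote on one regimen
   within a 15-day window; any split, or any member's explicit request,
   escalates.

The package treats the engine as a *pure function* of the case record:
identical input always yields the identical decision. This is an assumption
about scope, not about oncology — everything judgement-like lives either in
the rule table (data, editable, versioned) or in the face-to-face meeting
(out of the engine's hands).

## Stage classes

Guideline charts branch on coarse disease extent rather than on full TNM
stage-group numerals, so the engine uses a three-way class, total over all
84 valid TNM triples:

- `metastatic` iff M1;
- `early` iff T1–T2 with N0 (and M0);
- `locally_advanced` otherwise (M0 with T3/T4 or any nodal involvement).

This is the minimal grouping that separates the packaged reference cases
correctly. N2 subdivisions (a/b/c) are distinct enum members — they appear
in real stage strings and must round-trip — but classify identically to N2.
AJCC edition-specific stage groups (I–IVC), HPV status and performance
status are deliberately out of scope.

## The rule table and its provenance

The shipped table (`inst/extdata/rules.json`) is data, not code: every cell
can be inspected, and a different guideline snapshot can be swapped in via
`read_rule_table()` without touching the engine. Ten of the sixteen cells
are anchored directly to the packaged reference decisions (`anchored: true`
in the JSON). The remaining six follow the pattern those anchors establish:

- advanced non-nasopharyngeal disease offers surgery with adjuvant
  radiation or concurrent chemoradiation;
- the nasopharynx is never treated surgically (its characteristic UCNT
  histology is radio/chemosensitive and the site is surgically
  inaccessible), so both its cells are chemoradiation only;
- `floor_of_mouth/early` mirrors `oral_tongue/early` (single-modality
  surgery or radiation), the usual oral-cavity pattern;
- `tongue_base/early` mirrors `oropharynx/early`, tongue base being an
  oropharyngeal subsite.

Unanchored cells are flagged so a reviewer can see exactly which entries
rest on pattern-completion rather than a reference decision. Histology is
part of the lookup interface for forward compatibility, but no shipped cell
splits on it. Dose, fractionation, drug choice and neck-dissection extent
are out of scope.

Two escalation rules are absolute: M1 always escalates (the table carries no
automatic palliative pathway) and relapse always escalates (salvage is
exactly the kind of case an in-person meeting exists for).
`escalation_reasons()` reports *all* applicable triggers, evaluating the
feasibility check for M1 cases against the metastasis-independent (T/N)
table entry so that a report can say "metastatic, and no feasible option
either".

Poor-prognosis factors are recorded and carried into reports but consume no
rule: the case file names them as an input, no decision chart pins down how
they alter a recommendation, and silently inventing such a rule would be
worse than honestly ignoring them.

## Decision canonicalization and agreement

Free-text decision strings are parsed into canonical decision sets before
comparison: `and`/`+` combine modalities, `or` separates alternatives,
`A ± B` expands to two alternatives (with and without B), any
capitalization/pluralization of "face-to-face MDM" is the escalation, and
all unicode dash variants are normalized to ASCII. Within a regimen,
combinations without surgery are unordered (concurrent chemoradiation),
while sequences containing surgery keep their order — surgery with adjuvant
radiation is not radiation with salvage surgery. Alternatives are an
unordered set; rendering sorts them by length and then by fixed modality
order for stable output.

Cohen's κ is computed with each distinct canonical decision as one nominal
category — the only coding derivable from printed decision strings. Two
choices deserve emphasis:

- **No partial credit.** Overlapping but unequal option sets disagree. The
  packaged reference cases include a near-miss (engine "surgery + radiation
  or radiation" vs expert "surgery ± radiation") which this strict rule
  scores as disagreement; the headline agreement bound holds regardless, so
  the strict rule is retained rather than a fuzzier one that would need a
  similarity threshold nobody published.
- **Unweighted κ only.** A weighted κ needs an ordering or distance between
  decision categories that is not defined for treatment regimens.

Degenerate tables: with a single shared category and perfect agreement,
κ is defined as 1; with disagreement it is undefined and raised as an
error rather than returned as NaN. κ is clamped to exactly 1 whenever
observed agreement is perfect, so floating-point marginals cannot produce
0.9999…; the implementation is checked against a brute-force pairwise
oracle to 1e−12 in the tests.

Over the ten packaged reference cases the engine reproduces the automatic
column 10/10, and against the blinded expert column p₀ = 0.7 (7/10),
pₑ = 0.20, κ = 0.625 — substantial on the Landis–Koch bands, whose
interpretation thresholds (0 / 0.2 / 0.4 / 0.6 / 0.8) are hard-coded in
`interpret_kappa()`.

## Workflow semantics

The review record is a small state machine: `draft → pending →
{validated | escalated}`, with `draft → escalated` when the engine escalates
at submission. Closed records never reopen. Design choices where the
procedure was genuinely open:

- **Deadline boundary.** "Reviewed in no longer than 15 days" is read
  inclusively: a record is overdue strictly *after* submission + 15 days
  (`list_overdue()` at the deadline instant returns nothing). The window is
  a parameter (`review_window_days`, default 15 — matching a face-to-face
  cadence of every two weeks).
- **Any face-to-face vote escalates.** The request is offered to each
  member individually; once cast, unanimity on a regimen is impossible, so
  resolution short-circuits to escalation with reason `non_unanimous`.
- **Re-voting is allowed** until resolution (one vote per role, replacement
  semantics). Immutable votes would deadlock a board that changes its mind
  after an internal-mail exchange.
- **Proposed alternatives become votable options** visible to the other
  members, equal in standing to the engine's proposals.
- **Injected time.** Every operation takes its timestamp as an argument;
  nothing reads the wall clock. All workflow behavior is replayable in
  tests, and the fuzzer can drive thousands of reviews through arbitrary
  schedules deterministically.
- **No persistence layer.** Records are plain R objects serializable as
  JSON; a database is deployment, not method. Authentication, e-mail
  transport and meeting scheduling are likewise out of scope.

## The synthetic case generator

`generate_cases()` produces valid draft case files for property testing and
simulation. Defaults, chosen once: uniform sublocation weights; stage-class
mix 50% early / 40% locally advanced / 10% metastatic (mirroring the 5/4/1
composition of the packaged reference cases); per-modality infeasibility
10%; relapse 10%. TNM triples are drawn uniformly *within* the drawn stage
class, nasopharyngeal cases are always UCNT, and other sites are epidermoid
carcinoma 9:1 against other histologies. Sampling is seeded and restores
the caller's RNG state, so identical seeds give byte-identical case lists.

The generator emulates the *structural* surface of real rosters — valid
enum combinations, class-consistent stages, independent feasibility flags —
and nothing else. Real-world correlations (feasibility depends on stage and
comorbidity, relapse depends on site, histology mixes vary by region) are
absent, as are data-entry errors. Passing property tests therefore
demonstrates the engine's logical invariants (monotonicity, totality,
determinism) over the whole valid input space, not clinical performance on
real case mix.

## Problem sizes and numerical choices

The test suite runs the exhaustive 84-triple staging lattice, 300–1000
generated cases for monotonicity, 200 random samples against the κ oracle
(tolerance 1e−12, the only floating-point comparison in the package), all
16 rule-table cells for totality, and 10,000 randomized review sequences
for the state machine. These sizes make every property check exact or
effectively exhaustive at interactive runtimes. There are no iterative
numerics: ties cannot occur (decisions are sets), and the only tolerance is
the oracle comparison above.

## Known limitations

- The rule table is a reconstruction anchored to ten reference decisions,
  not a full transcription of any guideline edition; the six unanchored
  cells are best-effort pattern completion and flagged as such.
- Histology and poor-prognosis factors are carried but currently inert.
- Strict decision equality may undercount "clinical" agreement between
  overlapping option sets.
- κ over 10 items has wide sampling uncertainty; the package deliberately
  reports no confidence interval because none is defined for the published
  comparison it reproduces.
- The workflow models consensus logic only — no authentication, no
  attachment of reports to electronic records, no scheduler for the
  face-to-face meetings it escalates to.
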