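# octomdm

Rule-based decision support and triage for head-and-neck tumor boards
(multidisciplinary team meetings, MDMs).

Tumor boards are expensive and crowded: meeting time grows with caseload
while the minutes available per patient shrink. Much of the docket, however,
is routine — cases whose management follows directly from published
guidelines. `octomdm` implements a semiautomatic triage method for upper
aerodigestive tract cancers: a structured case file plus a guideline-style
rule table generate an automatic therapeutic proposal for routine cases,
while complex cases — relapse, metastatic disease, no feasible treatment, or
a non-unanimous faculty — are escalated to an in-person ("face-to-face")
meeting. The package is aimed at oncology-informatics researchers studying
MDM triage and at developers of tumor-board tooling.

## Method

A patient case is the tuple (sublocation, TNM stage, histology, per-modality
feasibility, relapse flag, poor-prognosis factors). TNM triples are grouped
into stage classes:

- *metastatic* iff M1;
- *early* iff T1–T2 with N0 (and M0);
- *locally advanced* otherwise.

A rule table `R : (sublocation, stage class) → {regimens}` holds the
guideline-backed candidate regimens, where a regimen is an ordered set of
modalities (surgery, radiation, chemotherapy; order encodes sequence, e.g.
surgery with adjuvant radiation). The engine's decision for case *c* is

```
decide(c) = face-to-face                      if relapse(c) or M1(c)
          = face-to-face                      if F(R(site, class), c) = ∅
          = options F(R(site, class), c)      otherwise
```

where `F` keeps the regimens whose every modality is feasible for the
patient. Proposals are then validated by the five consultant roles
(otolaryngologist, oncologist, radiotherapist, radiologist, pathologist)
within a 15-day review window; anything short of a unanimous vote escalates
the case as well.

Agreement between the engine and an expert over the same cases is measured
with unweighted Cohen's κ = (p₀ − pₑ)/(1 − pₑ) after canonicalizing both
decision strings (`"Radiation + chemotherapy"` ≡ `"Radiation and
chemotherapy"`; `"A ± B"` expands to two alternatives), with each distinct
canonical decision one nominal category and Landis–Koch interpretation
bands.

## Worked example

```r
library(octomdm)

case <- patient_case("demo-1", "floor_of_mouth", "T3N1M0",
                     "epidermoid_carcinoma", surgery_feasible = FALSE,
                     submitted_by = "resident_a")
decide(case)
#> <MDM decision> Radiation + chemotherapy

rec <- submit_case(case, "2023-01-01")
rec
#> <MDM review demo-1> status: pending
#>   engine: Radiation + chemotherapy
#>   deadline: 2023-01-16T00:00:00Z

for (r in consultant_roles())
  rec <- record_vote(rec, r, regimen("radiation", "chemotherapy"), "2023-01-05")
rec <- resolve_votes(rec)
generate_report(rec)
#> # MDM report — case demo-1
#> ...
#> **Outcome (validated): Radiation + chemotherapy**
```

A locally advanced floor-of-mouth tumor would ordinarily offer surgery with
adjuvant radiation *or* concurrent chemoradiation; with surgery infeasible
only chemoradiation survives, so the engine proposes it, the review opens
with a deadline 15 days after submission, and a unanimous faculty validates
the regimen.

The package ships ten reference cases with both the automatic and a blinded
expert's decision; the engine reproduces the automatic column 10/10, and
agreement with the expert is:

```r
fx <- load_table1_fixtures()
auto <- lapply(fx, function(f) decide(f$case))
expert <- lapply(fx, function(f) canonicalize_decision(f$expected_expert))
cohen_kappa(auto, expert)
#> Cohen's kappa = 0.625 (substantial); p_o = 0.700, p_e = 0.200, n = 10
```

κ = 0.625 means the engine and the expert agreed on 7 of 10 cases, well
above the 20% agreement expected by chance — substantial agreement on the
Landis–Koch scale.

## Command line

A thin CLI wraps the package:

```sh
Rscript inst/cli/octomdm.R decide case.json            # one case -> decision JSON
Rscript inst/cli/octomdm.R batch roster.csv            # whole roster
Rscript inst/cli/octomdm.R kappa pairs.csv             # decision_a/decision_b columns
Rscript inst/cli/octomdm.R simulate 100 --seed 7 --out roster.json
Rscript inst/cli/octomdm.R fixtures
```

## Further reading

The methods vignette (`vignettes/octomdm-methods.Rmd`) documents the rule
table and its provenance, the stage-class grouping, the canonicalization
dialect, the workflow's design choices and the synthetic case generator,
along with known limitations.
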