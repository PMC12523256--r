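---
title: "Rule-based AJCC staging of prostatectomy pathology data: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Rule-based AJCC staging of prostatectomy pathology data: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(prostaging)
```

## The problem

After radical prostatectomy, the prognostic stage group of the AJCC 8th
edition is assembled from five elements: pathologic T stage, nodal status
(N), distant metastasis (M), the WHO/ISUP Grade Group derived from Gleason
patterns, and the serum PSA concentration in ng/mL. In practice these
elements live in free-text pathology reports, are frequently missing
(M-stage almost always, PSA in more than half of reports), and are
sometimes internally inconsistent — a report may state pT3a while recording
extraprostatic extension (EPE) as absent, or state a Grade Group that
contradicts its own Gleason patterns. `prostaging` implements the full
downstream machinery for this setting: typed records with explicit missing
semantics, a prioritized staging rule engine, consistency validation, a
property-graph representation, an offline report extractor, a synthetic
corpus generator, and evaluation statistics.

## The staging model

The engine applies nine prioritized rules in fixed order; the first rule
whose conditions are all definitely true fires:

| # | Condition | Stage |
|---|-----------|-------|
| 1 | M1 (any T, any N, any GG, any PSA) | IVB |
| 2 | N1, M0 | IVA |
| 3 | Grade Group 5, N0, M0 | IIIC |
| 4 | T3/T4, N0, M0, GG 1–4 | IIIB |
| 5 | PSA ≥ 20, T1–T2, N0, M0, GG 1–4 | IIIA |
| 6 | T1–T2a, N0, M0, GG1, PSA < 10 | I |
| 7 | T1–T2, N0, M0, GG1, PSA < 20 | IIA |
| 8 | T1–T2, N0, M0, GG2, PSA < 20 | IIB |
| 9 | T1–T2, N0, M0, GG3–4, PSA < 20 | IIC |

PSA boundaries are half-open: PSA exactly 10 is IIA-eligible and exactly 20
is IIIA-eligible. T-code ranges follow AJCC conventions: "T3/T4" is
{T3, T3a, T3b, T4}; "T1–T2a" is all T1 subcategories plus T2 and T2a; bare
T2 satisfies "T1–T2" but not "T1–T2a".

**The IIA rule's lower PSA bound.** Tabulations of these criteria usually
write IIA as "PSA ≥ 10, < 20". Under the priority order that lower bound is
almost redundant — Stage I has already captured T1–T2a with PSA < 10 — but
keeping it leaves T2b/T2c, GG1, PSA < 10 unstageable, which the AJCC manual
assigns to IIA. Rule 7 therefore tests only PSA < 20; by priority it then
covers exactly the AJCC IIA definition, and the engine is total on complete
inputs. The test suite checks this against an independently written oracle
coded directly from the prognostic-group definitions over the exhaustive
720-combination grid.

### Missing data

Every record field is a concrete value or one of three missing kinds:
`not_mentioned`, `dash` (an explicit "-"), and `x_code` — a recorded but
uninformative TNM code such as pNx or pMx that keeps its literal token.
The distinction matters twice. For staging, all three kinds block a rule
that needs the field. For scoring, an x_code is a *value*: an extractor
that outputs "not mentioned" where the ground truth says "pMx" is wrong,
which is exactly the failure mode that inflates the Unknown class in
external evaluations of LLM extraction.

Because prostatectomy is performed for localized disease, a missing M-stage
is imputed as M0 before rule evaluation (`impute_m()`), with the imputation
recorded in the result. `pmx_policy = "block"` exempts the x_code kind from
imputation so that pMx blocks staging instead; both behaviours of the
reference pipeline are reproducible. Note that the graph round trip
(`stage_from_graph()`) is guaranteed only under the default policy: missing
fields produce no graph edge, so the graph cannot distinguish pMx from
"not mentioned".

When a rule's outcome cannot be decided because a field is missing, no
later rule may fire (its priority relative to the blocked rule is
uncertain); the result is `Unknown` with the union of blocking fields in
the fixed order T-Stage, N-Stage, M-Stage, Grade Group, PSA:

```{r unknown}
stage_label(stage_record(pathology_record(
  "P1", "R1", t_stage = "pT2c", m_stage = "cM0", psa_ng_ml = 5)))
```

Grade Group is taken from the reported WHO Grade Group when present, else
derived from the Gleason patterns (ISUP 2014: sum ≤ 6 → 1; 3+4 → 2;
4+3 → 3; sum 8 → 4; sum 9–10 → 5). A discrepancy between the two is never
resolved by the engine — it is the validator's finding.

## Consistency validation

Five rule families detect incoherent records, each silent when its fields
are missing: (1) T2-family stage with EPE present (EPE defines pT3a);
(2) SVI present at T2 or T3a (SVI defines pT3b); (3) N0 with positive
nodes / N1 without; (4) Gleason sum discordant with the reported Grade
Group; (5) T3b without SVI / T3a without EPE. Codes are descriptive strings
(`T2_stage_with_EPE_should_be_T3a`, `Gleason_7_inconsistent_with_GG3`, …).
The code `T3b_stage_but_no_SVI` has no published exemplar; it follows the
morphology of the T3a code. Summary percentages are reported both over
errors (the convention of an "n (%)" error-frequency table) and over the
corpus (flagged-case rate).

## The knowledge graph

Records and staging results are materialized as an in-memory property
graph with six node labels — Patient, Pathology_Report, TNM_Stage (unique
per code + category), Grade, PSA_Value (keyed by the value rounded to two
decimals), AJCC_Stage — and seven edge types (HAS_REPORT, HAS_T/N/M_STAGE,
HAS_GRADE, HAS_PSA, CLASSIFIED_AS). A fully populated record yields 8 nodes
and 7 edges (the three TNM categories are necessarily three distinct
nodes). No database runtime is required; `export_graph()` emits
deterministic JSON, GraphML, or a Cypher MERGE script for interoperability
with property-graph databases. The relationship name HAS_PSA is this
package's choice; sources describing the schema name the node but not the
edge.

## Extraction

`baseline_extract()` is a deterministic, regex-based stand-in for an LLM
extractor, exact on the renderer's three dialects. It exists so the whole
pipeline runs offline and so extraction scoring can be exercised with a
known-perfect extractor; wrapping an actual model is an integration
concern, served by `parse_extraction_json()`, which tolerantly parses
`{value, evidence, confidence}` JSON (stripping code fences and
commentary) and returns a structured failure — not an error — on malformed
output so callers can exclude those reports, mirroring how reports that
fail JSON conversion are excluded in practice. Baseline confidences are
binary (1.0 hit / 0.0 miss) because no calibration procedure is defined
for it. When a report states only the primary Gleason pattern's share
("60% pattern 4"), the secondary percentage is computed as its complement.

## The synthetic world

The generator's defaults emulate a 152-case internal prostatectomy series:
T-stage concentrated at pT2c (49%), pT3a (32%) and pT3b (15%); N-stage
76% pN0, 9% pN1, 15% pNx; M-stage recorded in only 2% of reports; Grade
Groups centred on GG2–GG3; PSA log-normal (meanlog log 8, sdlog 0.75,
median ≈ 8 ng/mL) — chosen because the asymmetric confidence interval of
the reference series' mean PSA indicates right skew; perineural invasion
present in ~92%. Missing rates per field follow the same series (e.g.
T-stage 3.9%, Grade Group 5.3%).

Coherence is enforced by construction and is deliberately *stricter* than
reality: EPE is present iff T ≥ T3a, SVI iff T3b/T4, positive nodes iff
N1, the reported Grade Group always equals the pattern-derived one, and
the secondary percentage complements the primary's. Real pT3b reports can
lack documented EPE; the strictness is what makes injected corruptions
identifiable (a `loose` flag decouples the invasion indicators for realism
studies). Reports render in three dialects — synoptic key:value lines,
narrative prose, and a tabulated Grade-Group grid whose correct row is
marked "X". Noise mode reproduces two documented failure modes: EPE phrased
only implicitly as a "small capsular defect" with "tumor infiltrates
forming margins", and omission of the Gleason percentage.

A green round-trip test therefore establishes that the extractor is exact
on *these templates*, not on institutional report language; the generator
does not attempt report headers, localized text, or free-form microscopic
descriptions. Corruption operators (`inject_inconsistency()`) minimally
edit a coherent record to trigger exactly one target error code, signalling
a typed condition when the target is impossible for that record so
harnesses can resample.

Multiple reports per patient follow a most-recent-report merge: the newest
report is the reference and earlier reports fill only its missing fields.

## Evaluation statistics

Field metrics treat a both-missing pair as correct for accuracy, but it
enters neither precision's denominator (non-missing predictions) nor
recall's (non-missing truths) — the only reading under which a field that
is missing everywhere and never falsely extracted scores accuracy 1 with
undefined precision, as published M-stage rows require. Matching is
case-folded, TNM-prefix-insensitive ("pT3a" equals "T3a"), numerically
tolerant to 0.01, and collapses all missing kinds except x_code. Staging
metrics collapse every "Unknown (Missing …)" label into one Unknown class,
compute one-vs-rest TP/FP/FN per class, and average per-class values
*unrounded* into the macro row — averaging the rounded cells does not
reproduce published macro rows (0.923 vs 0.922 in one case), so only the
unrounded reading is asserted. F1 is defined as 0 when precision + recall
is 0. Display rounding is half-up to 3 decimals (base R's `round()` is
half-to-even, which would print 2334/2400 as 0.972); stored values are
unrounded.

Wilson score intervals are computed in closed form. Fisher's exact test
enumerates the hypergeometric distribution directly for 2×2 tables
(two-sided: total probability of tables no more likely than observed) and
delegates r×2 tables to the exact network algorithm while a bounded
state-space estimate stays below 10^6, beyond which a seeded Monte-Carlo
p-value (10^5 replicates) with its standard error is returned. The Pearson
chi-squared test is applied without continuity correction. The mean-PSA
confidence interval sometimes attached to dataset summaries is *not*
implemented: its method (log-scale, bootstrap, …) is unstated, and a
guessed reproduction would be worse than none.

## Numerical and degenerate-input choices

* PSA exactly at a boundary: 10 → IIA-eligible, 20 → IIIA-eligible.
* Gleason patterns outside {3, 4, 5} are rejected at construction; patterns
  1–2 are obsolete under ISUP 2014 and silently accepting them would mask
  upstream extraction errors.
* `nodes_with_metastasis ≤ nodes_examined` is enforced at construction with
  an override (`allow_incoherent_counts`), because detecting incoherence is
  the validator's job, not the constructor's.
* An empty corpus yields empty (not failing) validation tables and an empty
  graph; an empty graph exports an empty Cypher script.
* Graph exports order nodes by (label, key) and edges by type and
  endpoints, so equal graphs export byte-identically.

## Workbook export

Results are exported as a directory of CSV sheets with fixed names
(`classification`, `consistency_errors`, `error_summary`, `field_metrics`,
`staging_metrics`) plus JSONL artifacts and a regeneration manifest. A
single-file spreadsheet workbook was not used because no xlsx writer is
available in the supported dependency set; the sheet names and contents
follow the workbook contract exactly. Pipeline configuration is JSON (not
YAML) for the same dependency reason.

## Known limitations

* Only the AJCC 8th edition and the prostate TNM vocabulary are supported.
* The baseline extractor is template-bound by design; its 100% round trip
  is a property of the synthetic dialects, not a claim about clinical text.
* The graph cannot represent the x_code/not-mentioned distinction (missing
  fields produce no edge), so `pmx_policy = "block"` is honest only on
  records, not through the graph.
* Validation does not flag Nx-like situations (e.g. N-stage asserted with
  zero nodes examined); only metastasis-count rules are implemented.
* No probabilistic scoring of validation findings; codes are categorical.
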