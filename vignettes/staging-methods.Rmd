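---
title: "Rule-based TNM staging for NSCLC reports: model, assumptions and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Rule-based TNM staging for NSCLC reports: model, assumptions and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tnmstager)
```

## The staging model

`tnmstager` encodes clinical (imaging-based) TNM staging of non-small
cell lung cancer as a deterministic, prioritized rule system over
structured report findings, together with the AJCC 8th-edition mapping
from (T, N, M) triples to clinical stage groups.

**T** is assigned by the first matching rule in a fixed priority order:
T4 triggers (diameter 50–70 mm with trans-lobar growth; invasion of a
T4-tier structure — diaphragm, mediastinum, heart, major vessels,
trachea, recurrent laryngeal nerve, esophagus, vertebral body, carina;
cancer nodules in a different ipsilateral lobe), then T3 triggers
(T3-tier invasion — parietal pleura, chest wall including Pancoast
tumors, phrenic nerve, pericardium, distal vessel main stems; an
isolated same-lobe cancer nodule; diameter under 50 mm with trans-lobar
growth), then T2 descriptors (atelectasis or obstructive pneumonia
extending to the hilum; invasion of a main bronchus or the visceral
pleura), then the pure size ladder in millimetres (≤10 → T1a, >10–20 →
T1b, >20–30 → T1c, >30–40 → T2a, >40–50 → T2b, >50–70 → T3, >70 → T4),
then explicit in-situ or minimally-invasive diagnoses, T0 when no
primary tumor is mentioned, and Tx when the tumor cannot be evaluated.
All thresholds are closed on the upper end (a 40 mm tumor is T2a, a
40.5 mm tumor T2b); lengths are canonically millimetres everywhere
inside the engine, centimetres are converted at the I/O boundary
(`canonical_mm()`).

**N** is the maximum tier among explicitly evidenced nodal stations
(N1: ipsilateral peribronchial / hilar / intrapulmonary; N2: ipsilateral
mediastinal, subcarinal; N3: contralateral mediastinal or hilar,
scalene or supraclavicular on either side).  Two conservative guards
apply: nonspecific descriptions (small nodes, mild FDG uptake) never
contribute a station, and a case without a PET-CT or contrast-enhanced
CT nodal assessment is Nx by construction — nodal status cannot be
judged from an inadequate modality.

**M** counts confirmatory extrathoracic lesions (≥2 → M1c, 1 → M1b) and
falls back to intrathoracic spread (pleural or pericardial metastatic
nodules, malignant effusions, contralateral lung nodules → M1a), then
Mx on explicit indeterminacy or inadequate imaging coverage, else M0.
What counts as "confirmatory" is the strategy switch described next.

### Strict versus lenient metastasis interpretation

Chinese radiology reports routinely mention incidental findings —
小结节 (small nodules), 低密度结节影 (low-density nodular shadows),
囊肿 (cysts) — that are poor evidence of metastasis.  The default
**strict** strategy accepts only high-specificity wording (转移性,
考虑转移, 疑似转移, 密度增高影, 高密度结节) as distant-lesion evidence;
the **lenient** comparator additionally promotes nonspecific findings in
distant organs to confirmatory evidence.  Both strategies share a
monotonicity guarantee, property-tested in the suite: for any findings,
the lenient M label never downstages the strict one.  The package
default is strict because false-positive M1 calls redirect a potentially
curative pathway toward palliative care; the lenient mode exists to
quantify exactly that risk (`scripts/acceptance.R` reports both
false-positive rates side by side).

### Stage grouping and degenerate triples

`group_stage()` applies, in order: the indeterminate rule (any of Tx,
Nx, Mx → `indeterminate`, with the single exception Tx N0 M0 →
`occult`, the occult-carcinoma triple), the metastasis rule (M1c → IVB,
M1a/M1b → IVA), Tis N0 M0 → stage 0, and the AJCC M0 grouping table.
The indeterminate rule deliberately precedes the metastasis rule, so
(Tx, N1, M1b) is `indeterminate` rather than IVA: a stage assignment
derived from a component that could not be evaluated would overstate
what the report supports.  Three corners of the 11×5×5 label product are
undefined in the AJCC manual — T0 with any N at M0, and Tis with nodal
disease at M0.  The engine maps these to `indeterminate` rather than
inventing a group; totality over all 275 triples is enforced by an
exhaustive test.  A bare T2 label (a descriptor-triggered T2 with no
size in the 30–50 mm range) is grouped as T2a, the convention that
keeps grouping total while preserving the class vocabulary.

### The T2 descriptor and size precedence

Read literally, a descriptor step that precedes the size ladder would
label a 60 mm tumor with atelectasis as T2, breaking monotonicity in
diameter.  The default mode `size_precedence` therefore applies the T2
descriptor only when the diameter is unknown or at most 50 mm, and
subdivides descriptor-T2 by size (30–40 mm → T2a, 40–50 mm → T2b) as
the guideline footnote prescribes.  The verbatim behaviour remains
available as `t2_descriptor_mode = "literal_box3"` for comparison.
Size monotonicity of the default mode is property-tested across the
whole diameter range.

## The extractor

The lexicon extractor is the deterministic analogue of a
report-understanding step: longest-match literal substring scanning
over normalized text, with no stemming and no learned components.
Design choices that matter:

- **Normalization** collapses whitespace runs, removes spurious single
  spaces between CJK characters and joins broken lines — the noise
  classes a photographed-report OCR step typically introduces.  It is
  idempotent (property-tested under a noise-injection oracle).
- **Negation** is clause-scoped: a match is negated when a cue (未见,
  未, 无, 不考虑; English: *no evidence of*, *without*, *no*, *not*)
  occurs within a preceding window of the same comma-delimited clause.
  The window defaults to 6 characters for Chinese and 30 for English,
  where cues sit further from their target ("no evidence of a primary
  tumor").  Negation rules are an extension beyond the term lists the
  staging rules specify; without them no extractor is usable.
- **Size guards**: a size phrase becomes a tumor measurement only when
  its sentence mentions the tumor itself (肿块, 肿瘤, 占位, 病灶 / mass,
  tumor, lesion) and carries no nonspecific-nodule wording, so the size
  of a "solid nodule" or an incidental liver lesion is never mistaken
  for the tumor diameter.  For `a×b` sizes the larger axis is the
  diameter; mm and cm dialects are both parsed.  When several
  measurements survive, `select_current_diameter()` prefers the
  highest-sequence measurement flagged as post-treatment — reports after
  therapy list historical sizes that must not drive staging.
- **Laterality**: mediastinal or hilar mentions without explicit
  laterality resolve to ipsilateral, the interpretation yielding the
  lower N tier.
- **Vertebral metastasis wording** (椎体转移) is treated as explicit
  invasion evidence for the vertebral body (a T4 site), not as a
  distant bone lesion — the anatomical reading of that phrase in
  thoracic reports.

Term lists live in editable YAML lexicons (`inst/extdata/`), one per
language, across seven categories (confirmatory/nonspecific metastasis,
invasion, confirmatory/nonspecific nodal, malignant nodule, negation
cues).  Anatomical gazetteers — lobe names, invasion-site surfaces,
nodal-station surfaces, distant-organ surfaces — are internal per-language
tables: they are vocabularies of anatomy, not evidence-grade term lists,
and swapping a lexicon must not silently change the anatomy model.

## The synthetic cohort generator

`generate_cohort()` is label-first: gold (T, N, M) triples are drawn
from the label distribution by stratified largest-remainder allocation,
then findings are sampled from each triple's preimage under the staging
rules.  Ground truth is therefore exact by construction — synthetic
truth replaces the consensus annotation a real study would use.  The
default configuration encodes the study design this generator emulates:

- `n_cases = 100` — the size of one held-out test cohort;
- `seed = 1102` — the default reproducibility seed;
- a uniform label distribution over the 250 default-reachable triples
  (all T labels except bare T2, crossed with all N and M labels),
  giving the "relatively balanced coverage of all subcategories" a
  staging evaluation needs; bare T2 and the minimally-invasive T1a path
  are excluded by default because they are reachable only through
  descriptor or explicit-diagnosis wording, not through the size
  ladder, and would make the round-trip non-unique;
- `modality_mix = (pet_ct 0.13, contrast_ct 0.85, neither 0.02)` — a
  CT-dominated mix with a PET-CT minority and a small remainder lacking
  an adequate nodal modality (an Nx target forces `neither`; any other
  N target draws from the first two, renormalized);
- `distractor_rate = 0.3` — the probability that a rendered report is
  salted with nonspecific distractor sentences in distant organs.

Diameters are drawn as integer millimetres strictly inside the target
bin (e.g. T2b ⇒ 41–50 mm), avoiding boundary ambiguity in rendered
text.  Rendering happens in a second pass after all findings are
sampled, so two cohorts with the same seed and different distractor
rates have identical structured findings — the paired design behind the
distractor-invariance test.  A `corruption_rate` produces a companion
prediction file whose labels are resampled uniformly *away from* gold
with the stated per-component probability, so the realized disagreement
rate equals the nominal rate (the binomial oracle the evaluation tests
use).

What the generator does **not** emulate: real reports' narrative
variability, OCR noise at the image level, longitudinal multi-report
patients, co-occurring findings that genuinely conflict, and the
correlation structure of real stage distributions.  A perfect
round-trip on synthetic cohorts therefore demonstrates internal
consistency of generator, extractor and engine — not clinical accuracy
on real reports.

## Evaluation statistics

- **Wilson score intervals** for accuracy.  The score interval is used
  because at n = 100 it reproduces the endpoint conventions of the
  published staging-evaluation literature this package's checks follow;
  endpoints are reported rounded to 3 decimals (`ci_low_3`/`ci_high_3`)
  with full precision retained alongside.
- **Macro averaging** is the unweighted arithmetic mean over *all*
  classes of the declared vocabulary, zero-score classes included — a
  class never predicted and never true contributes 0/0/0.
- **McNemar–Bowker**: χ² sums `(n_ij − n_ji)² / (n_ij + n_ji)` over
  unordered class pairs with any off-diagonal mass; df follows the
  full-pair convention k(k−1)/2 over the declared vocabulary, not only
  the occupied pairs, so df is a property of the task's label space.
  p-values use the asymptotic upper chi-square tail, and no
  multiple-testing adjustment is applied by default (a Holm correction
  can be applied downstream; the per-component p-values are reported
  raw).  At k = 2 the statistic is exactly classical McNemar without
  continuity correction — the suite asserts this identity against
  `stats::mcnemar.test()`.
- **Cohen ω** = √(χ²/n), with the conventional 0.1/0.3/0.5
  small/medium/large benchmarks attached.
- **Severity taxonomy**: pair-based and undirected.  The indeterminate
  rule (any Tx/Nx/Mx pair → III) precedes all pair rules, so T0↔Tx is
  III, not I.  Pairs the taxonomy tables leave unlisted — T2a↔T2b,
  bare-T2 pairs, Tis against invasive T labels — default to category II:
  they change the stage group (e.g. IB vs IIA, 0 vs I), which exceeds a
  "minimal impact" reading.  Context-conditional grading (using the
  co-occurring components of the same case) is a possible extension;
  the pair-based reading is the default because severity tallies must
  be reproducible from confusion matrices alone.

## Numerical and degenerate-input conventions

Zero denominators in precision/recall yield 0, not NaN; κ with
degenerate chance agreement (p_e = 1) returns 1 on perfect agreement
and 0 otherwise; empty Bowker pairs contribute 0 to χ²; an empty report
extracts to "no findings, coverage inadequate" and stages to Tx Nx Mx →
indeterminate — absence of text is never read as absence of disease.
Missing optional fields always default to the absent/false/unknown
value, never to a positive finding.

## Problem sizes in the test suite

The shipped tests stage two 500-case rendered cohorts end to end (the
round-trip and distractor-invariance checks), run ≥1000 strategy
monotonicity comparisons, 1200 oracle-equivalence instances
(precision/recall/F1, κ, and the k = 2 McNemar identity), and the
exhaustive 275-triple grouping and per-component pair enumerations.
These sizes were chosen so the full suite completes in about a minute
on one CPU while every property is exercised across its whole domain.

## Known limitations

- The extractor recognizes the shipped term lists and template-like
  phrasings; free-form clinical narrative, rare synonyms, or wording
  that mixes negation and assertion in one clause ("未见明确转移，但不除外")
  will be read conservatively, and co-occurring confirmatory and negated
  wording for the same organ is resolved toward the non-negated reading
  rather than flagged.
- Laterality resolution assumes a single primary tumor side; bilateral
  primaries are out of scope.
- Clinical staging only: no pathological or post-therapy staging, no
  small-cell or mesothelioma rules.
- The severity taxonomy is pair-based; a context-aware grading would
  need per-case stage-group computation on both triples.
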