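# tnmstager

Deterministic AJCC 8th-edition TNM staging for non-small cell lung cancer
(NSCLC) radiology reports, with the complete evaluation toolkit needed to
audit such an engine.

Clinical TNM staging assigns each case a primary-tumor label (T), a
regional-lymph-node label (N) and a distant-metastasis label (M), and
derives from the triple a clinical stage group (IA1–IVB, plus stage 0,
occult carcinoma and indeterminate).  `tnmstager` implements this as a
prioritized rule engine over structured report findings:

- **T**: T4 triggers (diameter 50–70 mm with trans-lobar growth, invasion
  of a T4-tier site, nodules in a different ipsilateral lobe), then T3
  triggers, then T2 descriptors (atelectasis/obstructive pneumonia to the
  hilum, T2-tier invasion), then the size ladder
  (≤10 T1a; >10–20 T1b; >20–30 T1c; >30–40 T2a; >40–50 T2b; >50–70 T3;
  >70 T4, all mm), then explicit in-situ diagnoses, T0 and Tx.
- **N**: the highest tier among explicitly evidenced stations (N3 > N2 >
  N1); nonspecific wording (e.g. "mild FDG uptake") never counts; without
  a PET-CT or contrast-CT assessment the status is Nx.
- **M**: ≥2 confirmatory extrathoracic lesions → M1c, exactly 1 → M1b,
  intrathoracic spread → M1a; under the default **strict** interpretation
  strategy only high-specificity wording (转移性 / 考虑转移 / 疑似转移 …)
  counts as lesion evidence, while the **lenient** strategy also accepts
  nonspecific findings (小结节, 低密度结节影, 囊肿 …) in distant organs.

Every staged case carries a rule-firing trace, so each label is justified
by the rule that produced it.

Around the engine the package provides:

- a bilingual (Chinese primary, English mirror) lexicon-based extractor
  turning free-text pseudo-reports into structured findings, with
  longest-match term scanning and clause-scoped negation;
- a clinical-impact error taxonomy grading each (truth, prediction)
  disagreement as a major (I), moderate (II) or minor (III) error;
- the full evaluation suite: confusion matrices, per-class and macro
  precision/recall/F1 (`prf()`), accuracy with Wilson score confidence
  intervals (`accuracy_ci()`), exact-match ratio, Cohen κ
  (`cohen_kappa()`), the paired McNemar–Bowker symmetry test
  (`bowker_symmetry()`, df = k(k−1)/2) and the Cohen ω effect size
  (`cohen_omega()`, ω = √(χ²/n));
- a label-first synthetic cohort generator (`generate_cohort()`): target
  (T, N, M) triples are drawn first and findings are sampled from each
  triple's preimage under the staging rules, so gold labels are exact by
  construction; rendered pseudo-reports can be salted with nonspecific
  distractor wording that must not change strict-mode staging.

## Worked example

```r
library(tnmstager)

# a 39 mm left-lower-lobe mass, no invasion, no nodules
tumor <- tumor_findings(list(measurement(39, 1)), lobe = "LLL")
stage_t(tumor)
#> $label
#> [1] "T2a"
#> $trace
#> [1] "t_not_evaluable=no"   "t4_triggers=no"       "t3_triggers=no"
#> [4] "t2_descriptor=no"     "fired:t_ladder_30_40"
```

The diameter exceeds 30 mm but not 40 mm and no higher-priority trigger
fires, so the 30–40 mm ladder rule assigns T2a.  The same case staged from
report text:

```r
case <- case_record("demo", report_text = "左肺下叶见恶性肿块，最大径约3.9cm。",
                    tumor = NULL, nodal = NULL, metastasis = NULL)
st <- stage_case(case)
format(st$tnm)
#> [1] "T2a Nx M0"
```

N is Nx because no nodal imaging modality was declared for the case
(without a PET-CT or contrast-CT assessment, nodal status is
undetermined), so the clinical stage group is `indeterminate`.

End to end on a synthetic cohort:

```r
cohort <- generate_cohort(sim_config(n_cases = 100, seed = 1102))
staged <- stage_cohort(cohort$cases, use_report_text = TRUE)
mean(staged$t == staged$gold_t & staged$n == staged$gold_n &
     staged$m == staged$gold_m)
#> [1] 1
```

On noiseless synthetic reports the engine recovers every generating label;
`evaluate_run()` on a deliberately corrupted prediction set exercises the
whole evaluation stack:

```r
cohort <- generate_cohort(sim_config(n_cases = 100, seed = 1103,
                                     corruption_rate = 0.1))
truth <- stage_cohort(cohort$cases)[, c("case_id", "t", "n", "m")]
evaluate_run(truth, cohort$predictions)
#> <eval_report> n = 100 cases
#>   T: accuracy 92.0% (95% CI 0.850-0.959), macro-F1 0.837, kappa 0.911, errors I/II/III = 5/3/0
#>   N: accuracy 86.0% (95% CI 0.779-0.915), macro-F1 0.862, kappa 0.825, errors I/II/III = 2/1/11
#>   M: accuracy 92.0% (95% CI 0.850-0.959), macro-F1 0.379, kappa 0.849, errors I/II/III = 5/0/3
#>   exact match 73.0%; clinical staging accuracy 84.0% (95% CI 0.756-0.899)
```

## Command line

```sh
inst/cli/tnmstager simulate --n 100 --seed 1102 --out cohort.jsonl
inst/cli/tnmstager stage    --in cohort.jsonl --out staged.jsonl --labels-out pred.csv
inst/cli/tnmstager evaluate --truth truth.csv --pred pred.csv --out report/
inst/cli/tnmstager impact   --truth truth.csv --pred pred.csv --component M --out impact.csv
```

Exit codes: 0 success, 2 usage, 3 validation, 4 I/O.  Every artifact gets
a manifest sufficient to re-run the command bit-identically.

## Scope

Clinical (imaging-based) staging only: no pathological (pTNM) or
post-therapy (yTNM) staging, no small-cell or mesothelioma rules, no
survival modelling, and no DICOM/HL7/FHIR or image ingestion.  The
extractor is a deterministic lexicon system, not a learned model.
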