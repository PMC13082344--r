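# English mirror of the default Chinese lexicon (see lexicon_zh.yaml for
# category semantics).  Terms are matched as literal substrings on
# normalized text, case-insensitively.
name: en-default
language: en
term_lists:
  metastasis_confirmatory:
    - metastatic
    - consider metastasis
    - suspected metastasis
    - metastasis
  metastasis_nonspecific:
    - small nodule
    - low-density nodule
    - dense shadow
    - high-density shadow
    - echogenic focus
    - softening focus
    - linear enhancement
    - cyst
  invasion_confirmatory:
    - invades
    - invasion
    - invading
    - encroachment
    - encroaches
    - occupies
    - occupying
  nodal_confirmatory:
    - lymph node metastasis
    - enlarged lymph node
    - markedly abnormal lymph node
  nodal_nonspecific:
    - mild fdg uptake
    - small lymph node
  malignant_nodule:
    - malignant soft tissue
    - cancer nodule
    - malignant nodule
  negation_cues:
    - "no evidence of"
    - without
    - "no "
    - "not "
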