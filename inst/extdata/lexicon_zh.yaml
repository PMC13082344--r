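# Default Chinese lexicon for radiology-report findings extraction.
# Category semantics:
#   metastasis_confirmatory - high-specificity metastasis wording; sufficient
#     evidence for a distant lesion under the strict strategy
#   metastasis_nonspecific  - common but nonspecific findings; evidence only
#     under the lenient strategy
#   invasion_confirmatory   - explicit invasion wording required before an
#     anatomical site counts as invaded
#   nodal_confirmatory      - explicit lymph-node metastasis wording
#   nodal_nonspecific       - cautious nodal descriptions (no station counts)
#   malignant_nodule        - wording strong enough to call a cancer nodule
#   negation_cues           - clause-scoped negation markers
name: zh-default
language: zh
term_lists:
  metastasis_confirmatory:
    - 转移性
    - 考虑转移
    - 疑似转移
    - 密度增高影
    - 高密度结节
  metastasis_nonspecific:
    - 小结节
    - 低密度结节影
    - 致密影
    - 高密度影
    - 强回声伴声影
    - 软化灶
    - 条状强化影
    - 囊肿
  invasion_confirmatory:
    - 侵犯
    - 侵及
    - 累及
    - 占据
    - 包绕
  nodal_confirmatory:
    - 淋巴结转移
    - 淋巴结肿大
    - 淋巴结明显异常
  nodal_nonspecific:
    - 小淋巴结
    - FDG轻度摄取
    - 轻度FDG摄取
  malignant_nodule:
    - 恶性软组织
    - 癌结节
  negation_cues:
    - 未见
    - 未
    - 无
    - 不考虑
    - 不伴
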