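# Cause-group definitions for death and hospital-admission records.
# ICD-9 ranges are inclusive 3-digit rubrics; ICD-10 ranges are inclusive
# letter+2-digit rubrics. Death causes carry both systems (coding era switches
# after 2002); admission causes are coded in ICD-9 only. washout_days: ~ means
# first-event-only; an integer enables the washout rule for repeat events.
death_causes:
  - cause_name: non_accidental
    record_type: death
    icd9: { ranges: [[1, 799]] }
    icd10: { ranges: [[A00, R99]] }
    search_scope: main_code_only
    washout_days: ~
  - cause_name: cvd
    record_type: death
    icd9: { ranges: [[390, 459]] }
    icd10: { ranges: [[I00, I99]] }
    search_scope: main_code_only
    washout_days: ~
  - cause_name: respiratory
    record_type: death
    icd9: { ranges: [[460, 519]] }
    icd10: { ranges: [[J00, J99]] }
    search_scope: main_code_only
    washout_days: ~
  - cause_name: neoplasm_excl_lung
    record_type: death
    icd9: { ranges: [[140, 239]], exclude: [[162, 162]] }
    icd10: { ranges: [[C00, D48]], exclude: [[C33, C34]] }
    search_scope: main_code_only
    washout_days: ~
  - cause_name: lung_cancer
    record_type: death
    icd9: { ranges: [[162, 162]] }
    icd10: { ranges: [[C33, C34]] }
    search_scope: main_code_only
    washout_days: ~
  - cause_name: nervous
    record_type: death
    icd9: { ranges: [[320, 359]] }
    icd10: { ranges: [[G00, G99]] }
    search_scope: main_code_only
    washout_days: ~
admission_causes:
  - { cause_name: circulatory,        icd9: { ranges: [[390, 459]] },                          search_scope: main_code_only, washout_days: ~ }
  - { cause_name: heart,              icd9: { ranges: [[390, 429]] },                          search_scope: main_code_only, washout_days: ~ }
  - { cause_name: cerebrovascular,    icd9: { ranges: [[430, 438]] },                          search_scope: main_code_only, washout_days: ~ }
  - { cause_name: respiratory,        icd9: { ranges: [[460, 519]] },                          search_scope: main_code_only, washout_days: ~ }
  - { cause_name: neoplasm_excl_lung, icd9: { ranges: [[140, 239]], exclude: [[162, 162]] },   search_scope: main_code_only, washout_days: ~ }
  - { cause_name: mental_behavioral,  icd9: { ranges: [[290, 319]] },                          search_scope: main_code_only, washout_days: ~ }
  - { cause_name: nervous,            icd9: { ranges: [[320, 359]] },                          search_scope: main_code_only, washout_days: ~ }
  - { cause_name: lung_cancer,        icd9: { ranges: [[162, 162]] },                          search_scope: main_code_only, washout_days: ~ }
  - { cause_name: bladder_cancer,     icd9: { ranges: [[188, 188]] },                          search_scope: main_code_only, washout_days: ~ }
  - { cause_name: kidney_cancer,      icd9: { ranges: [[189, 189]] },                          search_scope: main_code_only, washout_days: ~ }
  - { cause_name: diabetes,           icd9: { ranges: [[250, 250]] },                          search_scope: all_six_codes,  washout_days: ~ }
  - { cause_name: parkinson,          icd9: { ranges: [[332, 332]] },                          search_scope: main_code_only, washout_days: ~ }
  - { cause_name: alzheimer,          icd9: { ranges: [[331, 331]] },                          search_scope: main_code_only, washout_days: ~ }
  - { cause_name: MI,                 icd9: { ranges: [[410, 410]] },                          search_scope: main_code_only, washout_days: 28 }
  - { cause_name: angina,             icd9: { ranges: [[413, 413]] },                          search_scope: main_code_only, washout_days: 28 }
  - { cause_name: atherosclerosis,    icd9: { ranges: [[440, 440]] },                          search_scope: main_code_only, washout_days: ~ }
  - { cause_name: LRTI,               icd9: { ranges: [[466, 466], [480, 487]] },              search_scope: main_code_only, washout_days: 90 }
  - { cause_name: COPD,               icd9: { ranges: [[490, 492], [494, 494], [496, 496]] },  search_scope: all_six_codes,  washout_days: ~ }
  - { cause_name: asthma,             icd9: { ranges: [[493, 493]] },                          search_scope: main_code_only, washout_days: ~ }
  - { cause_name: miscarriage,        icd9: { ranges: [[634, 634]] },                          search_scope: main_code_only, washout_days: ~ }
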