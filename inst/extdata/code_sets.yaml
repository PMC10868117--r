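# Default diagnosis code sets, one per outcome. Illustrative ICD-10
# prefixes; real deployments should substitute locally curated lists
# (including institution-specific vocabularies) — the engine only needs
# (vocabulary, code, match) entries, where match is 'exact' or 'prefix'.
# An empty vocabulary matches records from any vocabulary.
aki:
  - {vocabulary: ICD-10, code: "N17", match: prefix}
hyperkalemia:
  - {vocabulary: ICD-10, code: "E87.5", match: prefix}
hypoglycemia:
  - {vocabulary: ICD-10, code: "E16.0", match: prefix}
  - {vocabulary: ICD-10, code: "E16.1", match: prefix}
  - {vocabulary: ICD-10, code: "E16.2", match: prefix}
hyponatremia:
  - {vocabulary: ICD-10, code: "E87.1", match: prefix}
anemia:
  - {vocabulary: ICD-10, code: "D50", match: prefix}
  - {vocabulary: ICD-10, code: "D51", match: prefix}
  - {vocabulary: ICD-10, code: "D52", match: prefix}
  - {vocabulary: ICD-10, code: "D53", match: prefix}
  - {vocabulary: ICD-10, code: "D55", match: prefix}
  - {vocabulary: ICD-10, code: "D56", match: prefix}
  - {vocabulary: ICD-10, code: "D57", match: prefix}
  - {vocabulary: ICD-10, code: "D58", match: prefix}
  - {vocabulary: ICD-10, code: "D59", match: prefix}
  - {vocabulary: ICD-10, code: "D60", match: prefix}
  - {vocabulary: ICD-10, code: "D61", match: prefix}
  - {vocabulary: ICD-10, code: "D62", match: prefix}
  - {vocabulary: ICD-10, code: "D63", match: prefix}
  - {vocabulary: ICD-10, code: "D64", match: prefix}
neutropenia:
  - {vocabulary: ICD-10, code: "D70", match: prefix}
thrombocytopenia:
  - {vocabulary: ICD-10, code: "D69.6", match: prefix}
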