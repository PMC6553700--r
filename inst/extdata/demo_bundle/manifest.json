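{
  "families": [
    {
      "family_id": "DEMO1",
      "n_generations": 3,
      "sibship_size_mean": 3,
      "penetrance": 1,
      "phenocopy_rate": 0,
      "genotype_missingness": 0.1,
      "founder_carrier": true,
      "min_affected_dna": 4,
      "n_background_variants": 12,
      "n_markers": 4,
      "seed": 71,
      "causal_key": "5:6684645:T:C"
    },
    {
      "family_id": "DEMO2",
      "n_generations": 3,
      "sibship_size_mean": 3,
      "penetrance": 1,
      "phenocopy_rate": 0,
      "genotype_missingness": 0.1,
      "founder_carrier": true,
      "min_affected_dna": 4,
      "n_background_variants": 12,
      "n_markers": 4,
      "seed": 72,
      "causal_key": "15:104015840:A:C"
    }
  ],
  "cohort": {
    "n_cases": 80,
    "n_controls": 80,
    "causal_maf_cases": 0.02,
    "causal_maf_controls": 0.002,
    "causal_reference_maf": 0.001,
    "n_background_variants": 8,
    "background_maf_range": [0.0001, 0.05],
    "seed": 70,
    "causal_key": "3:64283900:T:A"
  },
  "files": {
    "ped": "families.ped",
    "family_vcf": ["family_DEMO1.vcf", "family_DEMO2.vcf"],
    "markers": "markers.tsv",
    "frequencies": "frequencies.tsv",
    "cases_vcf": "cohort_cases.vcf",
    "controls_vcf": "cohort_controls.vcf",
    "counts": "cohort_counts.tsv"
  }
}
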