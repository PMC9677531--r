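{
  "version": "1.0",
  "description": "Structural contract of the runDemo report: required fields and scalar types.",
  "fields": {
    "config_hash": "string",
    "version": "string",
    "seed": "number",
    "phantom": {
      "gtv_volume_mm3": "number",
      "equivalent_diameter_mm": "number"
    },
    "plan": {
      "n_injections": "number",
      "total_volume_ul": "number",
      "total_activity_mbq": "number",
      "achieved_coverage": "number",
      "feasible": "logical"
    },
    "dosimetry": {
      "v60": "number",
      "v100": "number",
      "d95_gy": "number",
      "coverage_at_threshold": "number",
      "healthy_v10": "number"
    },
    "quantification": {
      "injected_ho_mass_mg": "number",
      "recovered_ho_mass_mg": "number",
      "calibration_slope": "number",
      "calibration_intercept": "number"
    },
    "survival": {
      "summary": "table",
      "logrank_treated_vs_untreated": {
        "statistic": "number",
        "p": "number",
        "p_reported": "string"
      }
    }
  }
}
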