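{
  "TIER1_CONDITIONS": "tier1_conditions.csv",
  "TIER2_CONDITIONS": "tier2_conditions.csv",
  "TRIGEMINAL_NEURALGIA": "trigeminal_neuralgia.csv",
  "HERPES_ZOSTER_ACUTE": "herpes_zoster_acute.csv",
  "POSTHERPETIC_NEURALGIA": "postherpetic_neuralgia.csv",
  "PHANTOM_LIMB_PAIN": "phantom_limb_pain.csv",
  "NEUROPATHIC_PAIN": "neuropathic_pain.csv",
  "AMPUTATION": "amputation.csv",
  "DIABETIC_NEUROPATHY": "diabetic_neuropathy.csv",
  "DIABETES": "diabetes.csv",
  "EPILEPSY": "epilepsy.csv"
}
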