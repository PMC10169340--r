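# Diagnosis code lists defining chronic health conditions.
# Physical health conditions use ICD-9-CM; mental health conditions use
# ICD-10. Pattern grammar: literal code; prefix ending in "x" (matches any
# suffix, including none); bare root (whole root family); inclusive range
# "A-B" over the integer root; decimal range over the full code value.
atrial_fibrillation:
  label: Atrial Fibrillation
  group: physical
  system: ICD9
  include: ["427.3x"]
cancer:
  label: Cancer
  group: physical
  system: ICD9
  include: ["140-239"]
  exclude: ["173", "209.40-209.9x", "210-224", "226-229", "232"]
chronic_lung_disease:
  label: Chronic Lung Disease
  group: physical
  system: ICD9
  include: ["491.x", "492.x", "494.x", "495.x", "496.x", "500-505"]
cad_angina:
  label: Coronary Artery Disease, Angina
  group: physical
  system: ICD9
  include: ["413.x"]
cad_mi:
  label: Coronary Artery Disease, History of Myocardial Infarction
  group: physical
  system: ICD9
  include: ["412.x"]
dementia:
  label: Dementia or Pre-Dementia
  group: physical
  system: ICD9
  include: ["331.x"]
diabetes:
  label: Diabetes Mellitus
  group: physical
  system: ICD9
  include: ["250.x", "357.2", "362.0", "366.41"]
epilepsy:
  label: Epilepsy
  group: physical
  system: ICD9
  include: ["345.x"]
heart_failure:
  label: Heart Failure
  group: physical
  system: ICD9
  include: ["398.91", "402.01", "402.11", "402.91", "404.01", "404.03",
            "404.11", "404.13", "404.91", "404.93", "425.x", "428.x"]
hypertension:
  label: Hypertension
  group: physical
  system: ICD9
  include: ["401.x", "402.x", "403.x", "404.x", "405.x"]
ibd:
  label: Inflammatory Bowel Diseases
  group: physical
  system: ICD9
  include: ["555.x", "556.x"]
osteoporosis:
  label: Osteoporosis
  group: physical
  system: ICD9
  include: ["733.0x"]
pad:
  label: Peripheral Arterial Disease
  group: physical
  system: ICD9
  include: ["440.x", "441-442", "443.89", "443.9"]
rheumatoid_arthritis:
  label: Rheumatoid Arthritis
  group: physical
  system: ICD9
  include: ["714.0"]
sleep_disorders:
  label: Sleep Disorders
  group: physical
  system: ICD9
  include: ["327.x"]
  exclude: ["327.35"]
stroke:
  label: History of Stroke
  group: physical
  system: ICD9
  include: ["438.x"]
vte:
  label: Venous Thromboembolism
  group: physical
  system: ICD9
  include: ["415.x", "453.x"]
alcohol_misuse:
  label: Alcohol Misuse
  group: mental
  system: ICD10
  include: ["F10.x"]
  exclude: ["F10.11", "F10.21"]
anxiety:
  label: Anxiety Disorders
  group: mental
  system: ICD10
  include: ["F41.x"]
adhd:
  label: Attention Deficit Hyperactivity Disorder
  group: mental
  system: ICD10
  include: ["F90.x"]
bipolar:
  label: Bipolar Disorder
  group: mental
  system: ICD10
  include: ["F31.x"]
depression:
  label: Depression
  group: mental
  system: ICD10
  include: ["F32.x", "F33.x"]
ptsd:
  label: Post Traumatic Stress Disorder
  group: mental
  system: ICD10
  include: ["F43.1"]
schizophrenia:
  label: Schizophrenia
  group: mental
  system: ICD10
  include: ["F20.x", "F25.x"]
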