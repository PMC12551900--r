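pt	category
DRUG INEFFECTIVE	Lack of efficacy
DISEASE PROGRESSION	Lack of efficacy
TREATMENT FAILURE	Lack of efficacy
THERAPEUTIC RESPONSE DECREASED	Lack of efficacy
PROSTATE SPECIFIC ANTIGEN INCREASED	Lack of efficacy
DRUG RESISTANCE	Lack of efficacy
NEOPLASM PROGRESSION	Lack of efficacy
FATIGUE	General complications
ASTHENIA	General complications
MALAISE	General complications
PYREXIA	General complications
OEDEMA PERIPHERAL	General complications
PAIN	General complications
DECREASED APPETITE	General complications
WEIGHT DECREASED	General complications
HOT FLUSH	General complications
CHILLS	General complications
PNEUMONIA	Infection
URINARY TRACT INFECTION	Infection
SEPSIS	Infection
INFLUENZA	Infection
COVID-19	Infection
CELLULITIS	Infection
NASOPHARYNGITIS	Infection
INFECTION	Infection
DIZZINESS	CNS
HEADACHE	CNS
SEIZURE	CNS
MEMORY IMPAIRMENT	CNS
COGNITIVE DISORDER	CNS
SYNCOPE	CNS
SOMNOLENCE	CNS
INSOMNIA	CNS
PARAESTHESIA	CNS
TREMOR	CNS
MENTAL STATUS CHANGES	CNS
VISION BLURRED	OPH/ENT
VISUAL IMPAIRMENT	OPH/ENT
TINNITUS	OPH/ENT
VERTIGO	OPH/ENT
CATARACT	OPH/ENT
DRY EYE	OPH/ENT
EPISTAXIS	OPH/ENT
HEARING IMPAIRED	OPH/ENT
DYSPNOEA	Respiratory
COUGH	Respiratory
INTERSTITIAL LUNG DISEASE	Respiratory
PLEURAL EFFUSION	Respiratory
RESPIRATORY FAILURE	Respiratory
WHEEZING	Respiratory
PNEUMONITIS	Respiratory
ARTHRALGIA	Musculoskeletal
BACK PAIN	Musculoskeletal
MYALGIA	Musculoskeletal
BONE PAIN	Musculoskeletal
MUSCULAR WEAKNESS	Musculoskeletal
FALL	Musculoskeletal
FEMUR FRACTURE	Musculoskeletal
MUSCLE SPASMS	Musculoskeletal
PAIN IN EXTREMITY	Musculoskeletal
HYPERTENSION	Vascular
ATRIAL FIBRILLATION	Vascular
MYOCARDIAL INFARCTION	Vascular
CARDIAC FAILURE	Vascular
DEEP VEIN THROMBOSIS	Vascular
CEREBROVASCULAR ACCIDENT	Vascular
HYPOTENSION	Vascular
TACHYCARDIA	Vascular
PULMONARY EMBOLISM	Vascular
GYNAECOMASTIA	Endocrine
HYPERGLYCAEMIA	Endocrine
DIABETES MELLITUS	Endocrine
HYPOTHYROIDISM	Endocrine
HYPOKALAEMIA	Endocrine
ADRENAL INSUFFICIENCY	Endocrine
HYPERKALAEMIA	Endocrine
NAUSEA	Gastro intestinal
DIARRHOEA	Gastro intestinal
VOMITING	Gastro intestinal
CONSTIPATION	Gastro intestinal
ABDOMINAL PAIN	Gastro intestinal
DYSPEPSIA	Gastro intestinal
GASTROINTESTINAL HAEMORRHAGE	Gastro intestinal
DYSPHAGIA	Gastro intestinal
ACUTE KIDNEY INJURY	Kidney/Urology
HAEMATURIA	Kidney/Urology
URINARY RETENTION	Kidney/Urology
RENAL FAILURE	Kidney/Urology
URINARY INCONTINENCE	Kidney/Urology
POLLAKIURIA	Kidney/Urology
BLOOD CREATININE INCREASED	Kidney/Urology
RASH	Skin
PRURITUS	Skin
ALOPECIA	Skin
DRY SKIN	Skin
HYPERHIDROSIS	Skin
ERYTHEMA	Skin
RASH MACULO-PAPULAR	Skin
TOXIC EPIDERMAL NECROLYSIS	Skin
URTICARIA	Skin
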