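diagnosis,indicated,contraindicated
insomnia,melatonin,benzodiazepine;z_drug
chronic_pain,paracetamol,pethidine
osteoarthritis,topical_nsaid,oral_nsaid_longterm
atrial_fibrillation,doac,digoxin_highdose
heart_failure_chronic,ace_inhibitor;beta_blocker,glitazone
osteoporosis_risk,vitamin_d;bisphosphonate,
depression_old_age,ssri,tricyclic_antidepressant
urge_incontinence,,oxybutynin
benign_prostatic_hyperplasia,alpha_blocker_uroselective,anticholinergic_urological
type2_diabetes_senior,metformin,glibenclamide
hypertension_senior,thiazide_lowdose;calcium_channel_blocker,clonidine
delirium_risk,,first_gen_antihistamine;benzodiazepine
gerd_chronic,ppi,
neuropathic_pain,gabapentinoid,tricyclic_antidepressant
anxiety_senior,ssri,benzodiazepine
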