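variable,kind,ci_low,ci_high,cutoff
gender,dichotomous,0.659,1.21,
emergency,dichotomous,1.44,6.57,
urgency,dichotomous,0.970,2.39,
blood_hypertension,dichotomous,0.987,1.87,
treated_diabetes,dichotomous,0.884,1.70,
acute_mi,dichotomous,1.57,6.38,
recent_mi,dichotomous,0.663,2.96,
preop_iabp,dichotomous,2.79,9.63,
tachycardia,dichotomous,0.885,5.47,
cardiogenic_shock,dichotomous,3.15,21.85,
cardiac_massage,dichotomous,0.988,21.62,
endocarditis,dichotomous,0.394,8.77,
unstable_angina,dichotomous,0.729,1.47,
heart_failure,dichotomous,1.90,5.25,
chronic_dialysis,dichotomous,3.51,36.70,
prev_cerebrovascular_events,dichotomous,0.998,3.01,
copd,dichotomous,1.07,2.80,
antiplatelet_drugs,dichotomous,0.545,0.984,
dicumarol_therapy,dichotomous,1.39,4.18,
heparin_therapy,dichotomous,0.873,1.57,
thrombolytic_therapy,dichotomous,0.125,3.88,
combined_cv_surgery,dichotomous,2.19,4.21,
repeated_cardiac_surgery,dichotomous,1.63,4.68,
aortocoronary_bypass,dichotomous,0.712,1.32,
plastic_valve_prosthesis,dichotomous,1.48,3.14,
valve_substitution,dichotomous,1.22,2.72,
aortic_valve_plasty,dichotomous,0.241,8.86,
aortic_valve_substitution,dichotomous,1.06,1.96,
tricuspid_valve_plasty,dichotomous,1.50,7.70,
non_isolated_cabg,dichotomous,1.52,2.74,
aortic_arch_pathology,dichotomous,0.776,4.30,
carotid_endarterectomy,dichotomous,0.382,2.55,
blood_added_to_cpb,dichotomous,1.96,3.59,
fresh_frozen_plasma,dichotomous,2.24,4.11,
significant_bleeding,dichotomous,0.728,1.39,
low_cardiac_output,dichotomous,12.3,23.9,
age,continuous,1.36,2.46,69
height,continuous,0.668,1.19,167
weight,continuous,0.587,1.05,71
body_surface_area,continuous,0.550,0.983,1.8
nyha_class,continuous,1.55,2.78,2
preop_hematocrit,continuous,0.499,0.895,39.2
preop_creatinine,continuous,1.51,2.69,1.0
preop_bilirubin,continuous,0.812,1.45,0.8
ecc_time,continuous,1.75,3.22,122
aortic_clamping_time,continuous,1.44,2.61,86
min_hematocrit_cpb,continuous,0.517,0.924,24
min_temperature,continuous,0.410,0.743,32.5
postop_hematocrit,continuous,0.570,1.02,31
postop_svo2,continuous,0.656,1.17,63.7
postop_creatinine,continuous,3.35,6.29,1.2
postop_bilirubin,continuous,1.99,3.70,1
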