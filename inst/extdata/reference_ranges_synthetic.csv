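institution,analyte,age_group,low,high,unit
site_a,creatinine,infant,18,35,umol/L
site_a,creatinine,toddler,21,36,umol/L
site_a,creatinine,early_childhood,27,48,umol/L
site_a,creatinine,middle_childhood,35,59,umol/L
site_a,creatinine,early_adolescence,44,88,umol/L
site_b,creatinine,infant,17,33,umol/L
site_b,creatinine,toddler,20,38,umol/L
site_b,creatinine,early_childhood,25,50,umol/L
site_b,creatinine,middle_childhood,33,62,umol/L
site_b,creatinine,early_adolescence,42,92,umol/L
site_a,potassium,infant,3.7,5.9,mmol/L
site_a,potassium,toddler,3.5,5.5,mmol/L
site_a,potassium,early_childhood,3.5,5.2,mmol/L
site_a,potassium,middle_childhood,3.5,5.0,mmol/L
site_a,potassium,early_adolescence,3.5,5.0,mmol/L
site_b,potassium,infant,3.9,5.6,mmol/L
site_b,potassium,toddler,3.6,5.2,mmol/L
site_b,potassium,early_childhood,3.5,5.0,mmol/L
site_b,potassium,middle_childhood,3.4,4.9,mmol/L
site_b,potassium,early_adolescence,3.4,4.9,mmol/L
site_a,glucose,infant,3.3,6.1,mmol/L
site_a,glucose,toddler,3.9,6.1,mmol/L
site_a,glucose,early_childhood,3.9,6.1,mmol/L
site_a,glucose,middle_childhood,3.9,6.1,mmol/L
site_a,glucose,early_adolescence,3.9,6.1,mmol/L
site_b,glucose,infant,3.3,6.0,mmol/L
site_b,glucose,toddler,3.9,6.4,mmol/L
site_b,glucose,early_childhood,3.9,6.4,mmol/L
site_b,glucose,middle_childhood,3.9,6.4,mmol/L
site_b,glucose,early_adolescence,3.9,6.4,mmol/L
site_a,sodium,infant,133,145,mmol/L
site_a,sodium,toddler,135,145,mmol/L
site_a,sodium,early_childhood,135,145,mmol/L
site_a,sodium,middle_childhood,135,145,mmol/L
site_a,sodium,early_adolescence,135,145,mmol/L
site_b,sodium,infant,132,144,mmol/L
site_b,sodium,toddler,135,144,mmol/L
site_b,sodium,early_childhood,135,144,mmol/L
site_b,sodium,middle_childhood,135,144,mmol/L
site_b,sodium,early_adolescence,135,144,mmol/L
site_a,anc,infant,1.5,8.5,10^9/L
site_a,anc,toddler,1.5,8.5,10^9/L
site_a,anc,early_childhood,1.5,8.0,10^9/L
site_a,anc,middle_childhood,1.8,8.0,10^9/L
site_a,anc,early_adolescence,1.8,7.5,10^9/L
site_b,anc,infant,1.5,8.2,10^9/L
site_b,anc,toddler,1.5,8.2,10^9/L
site_b,anc,early_childhood,1.5,7.8,10^9/L
site_b,anc,middle_childhood,1.6,7.8,10^9/L
site_b,anc,early_adolescence,1.6,7.2,10^9/L
site_a,hemoglobin,infant,105,135,g/L
site_a,hemoglobin,toddler,110,140,g/L
site_a,hemoglobin,early_childhood,115,145,g/L
site_a,hemoglobin,middle_childhood,115,150,g/L
site_a,hemoglobin,early_adolescence,120,160,g/L
site_b,hemoglobin,infant,100,130,g/L
site_b,hemoglobin,toddler,105,135,g/L
site_b,hemoglobin,early_childhood,110,140,g/L
site_b,hemoglobin,middle_childhood,115,145,g/L
site_b,hemoglobin,early_adolescence,115,155,g/L
site_a,platelets,infant,150,400,10^9/L
site_a,platelets,toddler,150,400,10^9/L
site_a,platelets,early_childhood,150,400,10^9/L
site_a,platelets,middle_childhood,150,400,10^9/L
site_a,platelets,early_adolescence,150,400,10^9/L
site_b,platelets,infant,180,420,10^9/L
site_b,platelets,toddler,180,420,10^9/L
site_b,platelets,early_childhood,180,420,10^9/L
site_b,platelets,middle_childhood,180,420,10^9/L
site_b,platelets,early_adolescence,180,420,10^9/L
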