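patient_id,sex,age,body_mass_index,smoking,hba1c_percent,hypertension,diabetes,hyperlipidemia,cancer,insomnia,region_category
P00001,male,57.2,23.1,no,5.6,TRUE,FALSE,FALSE,FALSE,FALSE,Kanto
P00002,female,61.4,,yes,,FALSE,TRUE,TRUE,FALSE,FALSE,Kinki
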