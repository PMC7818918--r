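patient_id,date,is_glaucoma_surgery_or_laser
P00001,2012-05-20,FALSE
P00002,2013-06-10,TRUE
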