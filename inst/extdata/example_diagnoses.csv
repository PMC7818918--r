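patient_id,date,icd10_code
P00001,2011-12-20,H401
P00001,2013-04-10,H401
P00002,2012-01-15,H409
P00002,2012-01-15,E119
P00002,2013-03-27,H409
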