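patient_id,dispense_date,generic_name,dosage_quantity,period_field
P00001,2012-01-10,latanoprost,2.5,1
P00001,2012-02-09,latanoprost,2.5,1
P00001,2012-03-10,latanoprost,7.5,3
P00001,2012-06-08,latanoprost,7.5,3
P00001,2012-09-06,latanoprost,7.5,3
P00001,2012-12-05,latanoprost,2.5,1
P00001,2013-01-04,latanoprost,2.5,1
P00001,2013-02-03,latanoprost/timolol,2.5,1
P00001,2013-03-05,latanoprost/timolol,2.5,1
P00001,2013-04-04,latanoprost/timolol,7.5,3
P00002,2012-02-01,timolol,5,1
P00002,2012-03-02,timolol,5,1
P00002,2012-04-01,timolol,15,3
P00002,2012-06-30,timolol,15,3
P00002,2012-09-28,timolol,15,3
P00002,2012-12-27,timolol,5,1
P00002,2013-01-26,timolol,5,1
P00002,2013-02-25,timolol,5,1
P00002,2013-02-25,brinzolamide,5,1
P00002,2013-03-27,timolol,5,1
P00002,2013-03-27,brinzolamide,5,1
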