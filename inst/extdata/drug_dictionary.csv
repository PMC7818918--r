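generic_name,class1,class2,is_fixed_combination,unit_bottle_volume,dosing_frequency
latanoprost,PG,,FALSE,2.5,once_daily
tafluprost,PG,,FALSE,2.5,once_daily
travoprost,PG,,FALSE,2.5,once_daily
bimatoprost,PG,,FALSE,2.5,once_daily
timolol,BB,,FALSE,5,twice_or_more_daily
carteolol,BB,,FALSE,5,twice_or_more_daily
dorzolamide,CAI,,FALSE,5,twice_or_more_daily
brinzolamide,CAI,,FALSE,5,twice_or_more_daily
brimonidine,AA,,FALSE,5,twice_or_more_daily
latanoprost/timolol,PG,BB,TRUE,2.5,once_daily
travoprost/timolol,PG,BB,TRUE,2.5,once_daily
tafluprost/timolol,PG,BB,TRUE,2.5,once_daily
dorzolamide/timolol,CAI,BB,TRUE,5,twice_or_more_daily
brinzolamide/timolol,CAI,BB,TRUE,5,twice_or_more_daily
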