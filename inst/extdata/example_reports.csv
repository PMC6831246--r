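report_id,is_initial,report_year,report_type,reporter,sex,age_years,causality,serious,seriousness_type,drugs,events,note
FX0001,TRUE,2016,other,consumer,female,15,possible,FALSE,none,S:S01LA05,endophthalmitis,
FX0002,TRUE,2016,spontaneous,doctor,male,62,probable,TRUE,other_including_death,S:S01LA05,endophthalmitis,
FX0003,TRUE,2015,spontaneous,doctor,male,68,possible,FALSE,none,S:S01LA05,endophthalmitis,
FX0004,TRUE,2015,post_marketing_surveillance,doctor,male,74,certain,TRUE,other_including_death,S:S01LA05,endophthalmitis,
FX0005,TRUE,2014,literature,doctor,male,81,probable,TRUE,hospitalization,S:S01LA05,endophthalmitis,
FX0006,TRUE,2016,spontaneous,doctor,female,62,possible,TRUE,other_including_death,S:S01LA05,endophthalmitis,
FX0007,TRUE,2016,post_marketing_surveillance,doctor,female,68,certain,TRUE,hospitalization,S:S01LA05,endophthalmitis,
FX0008,TRUE,2015,post_marketing_surveillance,pharmacist,male,74,probable,FALSE,none,S:S01LA05,endophthalmitis,
FX0009,TRUE,2014,spontaneous,pharmacist,male,81,possible,TRUE,hospitalization,S:S01LA05,endophthalmitis,
FX0010,TRUE,2013,spontaneous,nurse,male,62,certain,TRUE,other_including_death,S:S01LA05,endophthalmitis,
CT0001,TRUE,2016,spontaneous,doctor,missing,70,possible,FALSE,none,S:S01LA05,endophthalmitis,contaminant:missing_sex
CT0002,TRUE,2016,spontaneous,doctor,female,,possible,FALSE,none,S:S01LA04,retinal disorder,contaminant:missing_age
CT0003,TRUE,2016,spontaneous,doctor,male,66,possible,FALSE,none,S:,conjunctivitis,contaminant:missing_atc
CT0004,TRUE,2016,spontaneous,doctor,male,72,possible,FALSE,none,S:S01LA04,,contaminant:missing_event
CT0005,FALSE,2016,spontaneous,doctor,male,61,possible,FALSE,none,S:S01LA05,endophthalmitis,contaminant:followup
CT0006,TRUE,2016,spontaneous,doctor,male,68,unlikely,FALSE,none,S:S01LA04,retinal haemorrhage,contaminant:causality
CT0007,TRUE,2016,spontaneous,doctor,male,55,possible,FALSE,none,C:N02BE01,headache,contaminant:no_suspected_drug
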