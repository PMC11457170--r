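gas,lifetime_yr,report,horizon_yr,value,value_high,uncertainty
CO2,NA,AR4,100,1,NA,NA
CO2,NA,AR5,100,1,NA,NA
CO2,NA,AR6,100,1,NA,NA
CO2,NA,AR4,20,1,NA,NA
CO2,NA,AR5,20,1,NA,NA
CO2,NA,AR6,20,1,NA,NA
CH4_nonfossil,11.8,AR4,100,25,NA,NA
CH4_nonfossil,11.8,AR5,100,28,34,NA
CH4_nonfossil,11.8,AR6,100,27.2,NA,11
CH4_nonfossil,11.8,AR4,20,21,NA,NA
CH4_nonfossil,11.8,AR5,20,84,86,NA
CH4_nonfossil,11.8,AR6,20,80.8,NA,25.8
N2O,109,AR4,100,298,NA,NA
N2O,109,AR5,100,265,298,NA
N2O,109,AR6,100,273,NA,130
N2O,109,AR4,20,310,NA,NA
N2O,109,AR5,20,264,268,NA
N2O,109,AR6,20,273,NA,118
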