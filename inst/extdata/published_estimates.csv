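group,trait,parameter,estimate,se,reported_nonzero
heritability,rfi,h2_direct,0.42,0.09,TRUE
heritability,ch4_g_day,h2_direct,0.32,0.08,TRUE
heritability,ch4_ratio,h2_direct,0.29,0.06,TRUE
heritability,visceral_fat,h2_direct,0.93,0.19,TRUE
rfi_correlations,feeding_time_per_event,r_g,0.17,0.14,FALSE
rfi_correlations,intake_per_event,r_g,0.06,0.16,FALSE
rfi_correlations,events_per_day,r_g,0.13,0.16,FALSE
rfi_correlations,feeding_rate,r_g,-0.25,0.19,FALSE
rfi_correlations,intake_per_event,r_p,0.16,0.03,TRUE
rfi_correlations,visceral_fat,r_g,-0.52,0.16,TRUE
rfi_correlations,carcass_lean,r_g,0.06,0.18,FALSE
rfi_correlations,nonfat_viscera,r_g,0.64,0.13,TRUE
rfi_correlations,nonfat_viscera,r_p,0.33,0.04,TRUE
gas_correlations,rfi_x_ch4_ratio,r_g,-0.41,0.15,TRUE
gas_correlations,rfi_x_ch4_ratio,r_p,-0.13,0.03,TRUE
gas_correlations,intake_x_co2,r_g,0.59,0.14,TRUE
gas_correlations,intake_x_co2,r_p,0.47,0.02,TRUE
gas_correlations,mmwt_x_co2,r_g,0.62,0.13,TRUE
gas_correlations,mmwt_x_co2,r_p,0.45,0.02,TRUE
gas_correlations,ch4_x_carcass_lean,r_g,0.54,0.12,TRUE
gas_correlations,ch4_x_carcass_lean,r_p,0.28,0.03,TRUE
gas_correlations,ch4_x_nonfat_viscera,r_g,0.36,0.17,TRUE
gas_correlations,ch4_x_nonfat_viscera,r_p,0.12,0.04,TRUE
gas_correlations,ch4_x_intake_per_event,r_g,0.41,0.13,TRUE
gas_correlations,ch4_x_intake_per_event,r_p,0.26,0.03,TRUE
gas_correlations,ch4_x_feeding_rate,r_g,0.55,0.16,TRUE
gas_correlations,ch4_x_feeding_rate,r_p,0.23,0.03,TRUE
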