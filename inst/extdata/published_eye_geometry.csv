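species,radius_of_curvature_mean_mm,radius_of_curvature_sd_mm,facet_diameter_mean_um,facet_diameter_sd_um,alpha_min_mean_deg,alpha_min_sd_deg,n
Parasergestes armatus,0.3,0.02,26.0,4.1,10.8,2.1,4
Allosergestes sargassi,0.4,0.03,27.2,4.2,8.5,1.0,4
Deosergestes henseni,0.5,0.06,23.5,3.2,5.9,1.1,4
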