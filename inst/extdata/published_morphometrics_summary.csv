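species,sex,eye_diameter_mean_mm,eye_diameter_sd_mm,body_length_mean_mm,body_length_sd_mm,n
Parasergestes armatus,male,0.9,0.1,32,3,8
Parasergestes armatus,female,0.8,0.2,32,7,11
Allosergestes sargassi,male,0.7,0.1,23,1,10
Allosergestes sargassi,female,0.7,0.1,26,3,19
Deosergestes henseni,male,1.1,0.2,40,9,26
Deosergestes henseni,female,1.0,0.1,42,9,21
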