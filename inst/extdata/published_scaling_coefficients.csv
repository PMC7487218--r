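species,sex,n,log_intercept,slope
Parasergestes armatus,male,8,-0.72,0.44
Parasergestes armatus,female,11,-0.73,0.41
Allosergestes sargassi,male,10,2.4,-1.89
Allosergestes sargassi,female,19,-0.82,0.48
Deosergestes henseni,male,26,-0.75,0.48
Deosergestes henseni,female,21,-0.53,0.33
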