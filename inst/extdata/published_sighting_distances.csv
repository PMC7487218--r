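species,aperture_class,aperture_mm,emission_photons_per_s,distance_m
Parasergestes armatus,half,0.42,1e8,0.11
Parasergestes armatus,half,0.42,1e9,0.36
Parasergestes armatus,half,0.42,1e10,1.11
Parasergestes armatus,half,0.42,1e11,3.34
Parasergestes armatus,full,0.83,1e8,0.22
Parasergestes armatus,full,0.83,1e9,0.70
Parasergestes armatus,full,0.83,1e10,2.15
Parasergestes armatus,full,0.83,1e11,6.18
Allosergestes sargassi,half,0.36,1e8,0.10
Allosergestes sargassi,half,0.36,1e9,0.31
Allosergestes sargassi,half,0.36,1e10,0.96
Allosergestes sargassi,half,0.36,1e11,2.90
Allosergestes sargassi,full,0.72,1e8,0.20
Allosergestes sargassi,full,0.72,1e9,0.61
Allosergestes sargassi,full,0.72,1e10,1.88
Allosergestes sargassi,full,0.72,1e11,5.45
Deosergestes henseni,half,0.53,1e8,0.14
Deosergestes henseni,half,0.53,1e9,0.45
Deosergestes henseni,half,0.53,1e10,1.40
Deosergestes henseni,half,0.53,1e11,4.14
Deosergestes henseni,full,1.05,1e8,0.28
Deosergestes henseni,full,1.05,1e9,0.89
Deosergestes henseni,full,1.05,1e10,2.68
Deosergestes henseni,full,1.05,1e11,7.57
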