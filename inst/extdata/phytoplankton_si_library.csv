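group,tracer,mean,sd
Diatoms,d13C,-29.8,2.3
Diatoms,d15N,7.5,1.5
Chlorophytes,d13C,-23.7,2.6
Chlorophytes,d15N,8.7,2.0
Cyanobacteria,d13C,-25.8,3.0
Cyanobacteria,d15N,2.8,2.5
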