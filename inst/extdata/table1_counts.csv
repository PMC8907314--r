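species,site,N_i,N_g,N_nr,N_ns_printed,N_c_printed
B_auricomus,CC,56,54,54,56.0,84.0
B_auricomus,CW,NA,NA,NA,NA,NA
B_auricomus,ED,39,38,36,36.9,55.4
B_auricomus,SNR,44,38,36,41.7,62.5
B_bimaculatus,CC,1,1,NA,NA,NA
B_bimaculatus,CW,72,70,64,65.8,98.7
B_bimaculatus,ED,49,49,46,46.0,69.0
B_bimaculatus,SNR,38,34,33,36.9,55.3
B_griseocollis,CC,45,45,45,45.0,67.5
B_griseocollis,CW,12,12,NA,NA,NA
B_griseocollis,ED,61,56,54,58.8,88.2
B_griseocollis,SNR,34,32,32,34.0,51.0
B_impatiens,CC,53,48,45,49.7,74.5
B_impatiens,CW,42,42,41,41.0,61.5
B_impatiens,ED,71,64,58,64.3,96.5
B_impatiens,SNR,41,39,35,36.8,55.2
B_pensylvanicus,CC,39,38,28,28.7,43.1
B_pensylvanicus,CW,5,5,NA,NA,NA
B_pensylvanicus,ED,19,16,11,13.1,19.6
B_pensylvanicus,SNR,53,52,44,44.8,67.3
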