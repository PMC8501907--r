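# Varname map: Li-Cor 6400/6400XT export header -> canonical vocabulary.
# Transcribed from the LI-6400XT instruction manual column glossary.
# Edit freely: rows whose source column is absent from a file are ignored
# by read_gas_exchange().
canonical,source
A_net,Photo
Q,PARi
C_i,Ci
C_a,CO2S
g_sw,Cond
T_leaf,Tleaf
T_air,Tair
RH,RH_S
D,VpdL
phi_PSII,PhiPS2
J_F,ETR
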