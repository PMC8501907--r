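# Varname map: Li-Cor 6800 export header -> canonical vocabulary.
# Transcribed from the LI-6800 instruction manual column glossary.
canonical,source
A_net,A
Q,Qin
C_i,Ci
C_a,Ca
C_s,Cs
g_sw,gsw
T_leaf,Tleaf
T_air,Tair
RH,RHcham
D,VPDleaf
phi_PSII,PhiPS2
J_F,ETR
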