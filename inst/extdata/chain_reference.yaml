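# Reference parametrization of the brain-to-amplifier lumped-element model
# (impedance-spectroscopy-derived block values, implantation day).
R_S: 45.3 kOhm
R_E: 7.6 kOhm
R_F: 12.0 MOhm
C_H: 4.4 nF
R_Sh: 0.6 GOhm
C_Sh: 23.0 pF
R_Imp: 1.6 GOhm
C_Imp: 4.8 pF
R_Int: 12.4 MOhm
C_Int: 43.9 pF
R_Amp: 2.5 TOhm
C_Amp: 8.8 pF
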