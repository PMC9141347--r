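species	has_te
B_ovata	TRUE
B_bigemina	TRUE
B_bovis	FALSE
B_divergens	TRUE
T_equi	TRUE
C_felis	FALSE
T_orientalis	FALSE
T_parva	FALSE
T_annulata	FALSE
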