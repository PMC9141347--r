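species	has_te
E_tenella	TRUE
E_necatrix	TRUE
E_praecox	TRUE
E_acervulina	TRUE
E_mitis	TRUE
E_maxima	TRUE
E_brunetti	TRUE
E_falciformis	TRUE
E_nieschulzi	TRUE
C_cayetanensis	TRUE
C_suis	TRUE
H_hammondi	FALSE
T_gondii	FALSE
N_caninum	FALSE
B_besnoiti	FALSE
S_neurona	FALSE
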