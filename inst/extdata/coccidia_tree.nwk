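(((((((E_tenella,E_necatrix),E_praecox),(E_acervulina,E_mitis)),E_maxima),(E_brunetti,(E_falciformis,E_nieschulzi))),C_cayetanensis),(C_suis,((H_hammondi,T_gondii),(N_caninum,(B_besnoiti,S_neurona)))));
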