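# Default blood composition for the mechanistic Rb model.
# Representative values for human erythrocytes; every key can be
# overridden by a user file passed to read_blood_params().
hct: 0.45
f_rbc_water: 0.63
f_rbc_lipids: 0.005
f_rbc_prot: 0.33
k_prot: 0.2
ionization_correction: false
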