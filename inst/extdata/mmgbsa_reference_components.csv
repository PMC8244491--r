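complex,dE_vdW,dE_Ele,dE_Sol,dG_gas_printed,dG_bind_printed
citronellal_control,-26.28,-0.87,7.3753,-27.15,-19.78
pentadecanoic_acid,-40.20,-8.20,12.42,-48.41,-35.98
hexadecanedioic_acid,-39.28,-40.27,42.19,-79.55,-37.36
methylhexadecanoic_acid_14,-45.84,-2.21,8.27,-48.06,-39.78
hydroxytetradecanoic_acid_2,-33.50,-26.03,23.05,-59.54,-36.48
palmitic_acid,-41.57,-18.49,17.86,-60.06,-42.19
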