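porosity,E_eff_GPa
0.371,35
0.3,43
0.164,65
0.041,89
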