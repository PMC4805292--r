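# pmfkd window metadata (path center_A spring)
# energy_unit: kT
# bias_convention: half-k
# temperature_K: 298.14999999999998
toy_01.dat 0 2
toy_02.dat 1.5 2
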