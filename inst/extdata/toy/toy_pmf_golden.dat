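# pmfkd PMF table (z_A W_kT sigma_kT)
# zero_convention: bulk
# temperature_K: 298.14999999999998
# n_rows: 10
-1.75 Inf NaN
-1.25 1.479830037 NaN
-0.75 -0.4027340135 NaN
-0.25 0.02616724512 NaN
0.25 -0.01556666973 NaN
0.75 -0.1710099547 NaN
1.25 -0.452539455 NaN
1.75 0.04645404941 NaN
2.25 -0.002190227647 NaN
2.75 0 NaN
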