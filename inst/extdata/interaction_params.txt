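# segment interaction parameters, v1
temperature 298.14999999999998  # K
a_eff 7.5  # A^2
c_misfit 4593.1170986666666  # kJ mol^-1 A^-2 (e/A^2)^-2
c_hb 47742.229333333336  # kJ mol^-1 A^-2 (e/A^2)^-2
sigma_hb 0.0082000000000000007  # e/A^2
hb_form donor_acceptor  # donor_acceptor | product_threshold
combinatorial_form none  # none | area_volume
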