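# Lysis-budget worked example: lysate growth yield and coculture
# proliferation inputs (units in comments).
cfu_in_lysate: 170000000.0     # 1.7e8 CFU/ml reached in 48 h in algal lysate
cfu_baseline: 0.0              # matched no-carbon monoculture baseline, CFU/ml
lysed_algal_density: 1600000.0 # 1.6e6 algal cells/ml lysed into the lysate
observed_proliferation: 11000000.0  # 1.1e7 CFU/ml coculture bacterial increase
algal_density: 6100000.0       # 6.1e6 cells/ml coculture algal population
measured_lysis_range_pct: [1.0, 3.0]  # cytotoxicity-assay lysis range, %
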