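lightRegime: diurnal_12_12
durationH: 72.0
algalN0: 1000000.0
algalK: 4000000.0
algalDoublingH: 8.0
bacterialN0: 1000000.0
exudationRate: 0.04
lysisFractionPerDay: 0.008
bacterialYieldPerLysedCell: 100.0
bacterialYieldPerUgNPOC: 1400000.0
bacterialGrowthRate: 0.12
biomassYieldFactor: 0.012
reductiveDivisionMax: 3.0
labelStartH: 13.0
f15NSubstrate: 0.4968283
f13CSourceMax: 0.35
b12OnsetH: 24.0
cellLengthMaxUm: 2.3
cellLengthMinUm: 1.25
seed: 1
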