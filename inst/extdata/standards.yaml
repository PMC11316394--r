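# Natural-abundance instrument standard ratios and label composition.
RstdC: 0.02247          # 12C13C- / 12C2-
RstdN: 0.00367          # 12C15N- / 12C14N-
label15NPurity: 0.99    # atom fraction 15N of the labeled ammonium
substrateMixingFraction: 0.5  # fraction of medium ammonium labeled
carbonConvention: dimer # random-pairing dimer model, p = R/(2+R)
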