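# Synthetic 160-nt neutral padding sequence: AU/GC-balanced (GC 0.456),
# no periodic-AUUUA run of length >= 5 and no UUCYRYGAA core. Generated once
# from a seeded composition sampler and frozen here.
NEUTRAL_PAD <- paste0(
  "UAGCUGUUCCACCGUUAAUUGCUCAGGUCUUCAUAAAAUUUCGCUCAAGUGACCAGUCCUGUAGGGAUUGCC",
  "UGCGUUAGAGAUUCUUUGUCCCAUUGGCCGUCCUACCUAAUAAAGACCCGAAGGCUUUUAUAGACCGCGGUA",
  "GAUGUACUGAGUUACA"
)
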