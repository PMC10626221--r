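{
  "A": ["polysomy 3", "polysomy 15", "polysomy 19"],
  "B": ["polysomy 5", "polysomy 6", "polysomy 7", "polysomy 9", "polysomy 11", "polysomy 18", "polysomy 21", "11q loss", "TP53 loss"],
  "C": ["chromosome 2 loss"],
  "D": ["4q loss", "X loss"],
  "E": ["polysomy 8", "20q loss"],
  "F": ["polysomy 6"],
  "G": ["polysomy 16", "chromosome 10 loss"],
  "H": ["polysomy 21"],
  "I": ["polysomy 11", "polysomy 15", "polysomy 19", "chromosome 4 loss"],
  "1": ["ZNF676 c.1564G>T", "PRPF3 c.11C>A"],
  "2": ["GPC3 c.352G>T", "GPC3 c.355G>T", "KMT2C c.2576G>T", "KDR c.409T>G"],
  "3": ["ATM c.1262C>A"]
}
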