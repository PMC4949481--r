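# Standard curation for the mini-yeast host, in the same declarative form a
# genome-scale model would use: merge exact duplicate reactions (uniting
# isoenzyme gene rules with 'or') and disallow secretion of cytotoxic
# acetaldehyde (uptake direction untouched).
- kind: merge_duplicates
- kind: block_secretion
  exchange: EX_acald
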