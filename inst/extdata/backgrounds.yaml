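# Pre-selected deletion backgrounds for background-constrained knockout
# screening, specified by gene and mapped to reactions at run time through
# the model's gene-reaction rules (mapBackgroundGenes). The first set couples
# the glycine-serine pathway with growth; the second reroutes flux around the
# TCA cycle. Note that deleting a single isoenzyme gene (e.g. PYC1 with PYC2
# present) disables no reaction; that is the intended gene-rule semantics.
- name: glycine_serine
  genes:
    - SDH3
    - SER3
    - SER33
- name: tca_reroute
  genes:
    - ICL1
    - KGD1
    - PYC1
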