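# Heterologous pathway table, one reaction per line, grouped by product.
# Columns: product, reaction_id, equation, lb, ub, gene_rule, notes.
# Equations use signed-arrow notation with compartment suffixes (_c cytosol,
# _e extracellular); "<->" marks reversible reactions. A product exchange
# (and, if the pathway stops in the cytosol, a transport step) is synthesized
# when absent: here each pathway ends at <product>_c, so <PRODUCT>t and
# EX_<product> are added on load.
product	reaction_id	equation	lb	ub	gene_rule	notes
prdA	PWY_A	2 accoa_c + nadph_c -> prdA_c	0	1000	phaB	acetyl-CoA-derived polyester precursor
prdB	PWY_B	e4p_c + pyr_c + atp_c -> prdB_c	0	1000	aroX	erythrose-4-phosphate-derived aromatic precursor
prdC	PWY_C	pyr_c + nadh_c -> prdC_c	0	1000	ldhA	NADH-consuming reduced product
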