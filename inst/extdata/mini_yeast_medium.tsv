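# Minimal glucose medium: glucose as sole carbon source, oxygen uptake
# capped so overflow metabolism is active at optimum, free ammonium.
# Uptake/secretion limits are magnitudes in mmol/gDW/h.
exchange	max_uptake	max_secretion	carbon_source
EX_glc	10	0	1
EX_o2	2	0	0
EX_nh4	1000	0	0
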