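locus	motif	min_seed_units
AJ-1	TG	3
AJ-8	TG	3
AJ-9	TG	3
AJMS-3	TG	3
AJMS-6	TG	3
AJMS-10	GA	3
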