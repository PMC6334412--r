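library	raw_reads	high_quality_reads	clean_reads	unique_tags	mapped_reads	mapped_unique
HIST	28667031	28122819	27877781	1066655	20847175	584229
NC	21372487	20988298	20658317	1056485	14488689	594634
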