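# aligners reporting a taxon name and an E-value (lower is better)
read_id_col = 1
label_col = 2
score_col = 3
label_kind = name
score_direction = lower_better
ambiguity = none
unresolved = fp
header = false
method_name = name_evalue
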