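# tools emitting a semicolon-separated name lineage plus a reliability score
read_id_col = 1
label_col = 2
score_col = 3
label_kind = lineage
score_direction = higher_better
lineage_sep = ;
unresolved = fp
header = false
method_name = semicolon_lineage
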