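# similarity classifiers flagging multi-taxon calls as AMBIGUOUS(a;b;...)
read_id_col = 1
label_col = 2
score_col = 3
label_kind = name
score_direction = higher_better
ambiguity = list
ambig_marker = AMBIGUOUS
ambig_sep = ;
unresolved = fp
header = false
method_name = ambiguous_list
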