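# k-mer classifiers reporting a taxid and a confidence / k-mer fraction
read_id_col = 1
label_col = 2
score_col = 3
label_kind = taxid
score_direction = higher_better
ambiguity = none
unresolved = fp
header = false
method_name = taxid_confidence
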