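source	consequence
nonsynonymous snv	missense
missense_variant	missense
missense_mutation	missense
stopgain	nonsense
stopgain snv	nonsense
stop_gained	nonsense
nonsense_mutation	nonsense
splicing	splicing
splice_site	splicing
splice_acceptor_variant	splicing
splice_donor_variant	splicing
frameshift insertion	frameshift_indel
frameshift deletion	frameshift_indel
frameshift substitution	frameshift_indel
frameshift_variant	frameshift_indel
frame_shift_del	frameshift_indel
frame_shift_ins	frameshift_indel
nonframeshift insertion	inframe_indel
nonframeshift deletion	inframe_indel
nonframeshift substitution	inframe_indel
inframe_insertion	inframe_indel
inframe_deletion	inframe_indel
in_frame_del	inframe_indel
in_frame_ins	inframe_indel
synonymous snv	synonymous
synonymous_variant	synonymous
silent	synonymous
stoploss	other
stop_lost	other
start_lost	other
translation_start_site	other
unknown	other
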