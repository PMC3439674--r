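# Word stems in which "ill" is pronounced [il] (plain l), not [j]:
# the "ill" -> 6 rule is skipped for words starting with one of these stems.
ville
mille
tranquill
bacill
oscill
distill
maxill
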