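id	parent_id	start_in_parent
BP12N	BP12	2
BP12M	BP12	5
BP22M	BP22	3
BP22C	BP22	5
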