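id	field	reason
BP19.5	mw	tail-row cycle: printed value belongs to BP20.5
BP19.5	pi	tail-row cycle: printed value belongs to BP20.5
BP19.5	gravy	tail-row cycle: printed value belongs to BP20.5
BP20.5	mw	tail-row cycle: printed value belongs to BP21.5
BP20.5	pi	tail-row cycle: printed value belongs to BP21.5
BP20.5	gravy	tail-row cycle: printed value belongs to BP21.5
BP21.5	mw	tail-row cycle: printed value belongs to BP22.5
BP21.5	pi	tail-row cycle: printed value belongs to BP22.5
BP21.5	gravy	tail-row cycle: printed value belongs to BP22.5
BP22.5	mw	tail-row cycle: printed value belongs to BP19.5
BP22.5	pi	tail-row cycle: printed value belongs to BP19.5
BP22.5	gravy	tail-row cycle: printed value belongs to BP19.5
BP22C	pi	printed 5.80; ProtParam-consistent value for DSKIMF is 5.84
BP24	aromatic_n	printed 0; STTSLRVLGRDLFE contains one F
BP14.5	aromatic_n	printed 2; EIANFMLSESHF contains F,F,H
BP15N	aromatic_n	printed 1; LSESHF contains H,F
BP15M	aromatic_n	printed 2; SHFPYV contains H,F,Y
BP15C	aromatic_n	printed 1; YVLFLE contains Y,F
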