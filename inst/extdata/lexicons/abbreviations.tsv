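b.i.d.	Frequency	twice a day	RP12H
t.i.d.	Frequency	three times a day	RP8H
q.d.	Frequency	once a day	RP1D
q.i.d.	Frequency	four times a day	RP6H
q6h	Frequency	every 6 hours	RP6H
q8h	Frequency	every 8 hours	RP8H
q.h.s.	Frequency	nightly	RP1D
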