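Halloween
Christmas
Thanksgiving
Easter
New Year's Day
New Year's Eve
Independence Day
Labor Day
Memorial Day
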