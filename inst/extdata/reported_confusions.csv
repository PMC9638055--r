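system,gold_type,pred_date,pred_duration,na
chrono_ttd,DATE,383,29,48
chrono_ttd,DURATION,19,298,20
msra,DATE,413,20,21
msra,DURATION,48,272,17
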