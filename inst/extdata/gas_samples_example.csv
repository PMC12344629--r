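chamber_id,date,minutes,n2o_ppb
jar01,2025-06-01,0,331.2
jar01,2025-06-01,10,342.5
jar01,2025-06-01,20,352.9
jar02,2025-06-01,0,329.8
jar02,2025-06-01,10,336.1
jar02,2025-06-01,20,343.4
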