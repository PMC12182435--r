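SLA-1*07:02 + SLA-1*13:01 + SLA-1*12:01^SLA-2*10:01 + SLA-2*02:02^SLA-3*05:02 + SLA-3*04:02^SLA-DRB1*10:01 + SLA-DRB1*04:03^SLA-DQB1*06:01 + SLA-DQB1*03:03^SLA-DQA*02:04 + SLA-DQA*01:01^SLA-DRA*02:01 + SLA-DRA*04:01
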