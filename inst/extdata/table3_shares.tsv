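db	class_share_pct
0	1.3
1	37.9
2	43.1
3	17.7
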