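db	class_share_pct
0	2.5
1	17.0
2	65.3
3	15.2
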