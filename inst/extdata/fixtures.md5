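table2.tsv	71eb8f141612e92446e335554b5c5ea5
table3.tsv	06c766434f9b5dec8bf83e980de35220
table4.tsv	a1c123f19c9102343c5f0a3b9b0b600d
table3_shares.tsv	2825dd77e612215b02f150c6cf8615cd
table4_shares.tsv	956f2bc3580d2fc2e97d310daa7ba6bc
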