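age_group,sex,count
2-5,male,1536000
2-5,female,1458000
6-11,male,2304000
6-11,female,2187000
12-15,male,1536000
12-15,female,1458000
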