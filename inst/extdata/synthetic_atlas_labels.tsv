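label_id	region_name
1	region_01
2	region_02
3	region_03
4	region_04
5	region_05
6	region_06
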