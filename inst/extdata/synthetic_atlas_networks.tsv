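region_name	network
region_01	DMN
region_02	visual
region_03	cognitive
region_04	subcortical
region_05	DMN
region_06	visual
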