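# Example run configuration for dcslet stage functions
energy: 150
scenario: four_trimmer_GRID
offset: 0.025
histories: 100000
seed: 7
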