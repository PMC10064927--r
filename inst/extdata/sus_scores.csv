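expert,score
expert 1,95.0
expert 2,90.0
expert 3,87.0
expert 4,87.5
expert 5,87.5
expert 6,85.0
expert 7,85.0
expert 8,82.5
expert 9,75.0
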