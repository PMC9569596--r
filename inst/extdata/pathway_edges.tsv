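enzyme	step	precursor	product
SCD1	desaturase	16:0	16:1
SCD1	desaturase	18:0	18:1
ELOVL6	elongase	16:0	18:0
ELOVL3	elongase	20:1	22:1
ELOVL3	elongase	22:1	24:1
ELOVL5	elongase	18:3n-6	20:3n-6
ELOVL5	elongase	20:5n-3	22:5n-3
FADS2	desaturase	18:2n-6	18:3n-6
FADS2	desaturase	18:3n-3	18:4n-3
FADS1	desaturase	20:3n-6	20:4n-6
FADS1	desaturase	20:4n-3	20:5n-3
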