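RING_COMPLEX	toy ring module members plus two bystanders	G0001	G0002	G0003	G0004	G0005	G0006	G0020	G0021
CHAIN_COMPLEX	toy chain members plus one bystander	G0007	G0008	G0009	G0010	G0011	G0012	G0022
BACKGROUND_SET	genes outside the toy network	G0101	G0102	G0103	G0104
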