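condition	sd
pro11	0.62
pp2Ac1pro22	0.67
pro11pro22	0.57
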