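# replay schedule: channel (1-based), t_open, t_close in seconds
channel	t_open	t_close
6	0.005	0.100
7	0.020	0.080
10	0.040	0.110
11	0.060	0.140
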