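ID CTCF_core_synthetic
P0	A	C	G	T
01	  1	100	  1	  1
02	  1	100	  1	  1
03	100	  1	  1	  1
04	  1	100	  1	  1
05	  1	  1	  1	100
06	100	  1	  1	  1
07	  1	  1	100	  1
08	  1	  1	100	  1
09	  1	  1	100	  1
10	  1	  1	100	  1
11	  1	  1	100	  1
12	  1	100	  1	  1
13	  1	  1	100	  1
14	  1	100	  1	  1
//
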