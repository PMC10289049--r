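tg_lo	tg_hi	nonhdl_lt100	nonhdl_100_129	nonhdl_130_159	nonhdl_160_189	nonhdl_190_219	nonhdl_ge220
400	800	11.9	10.0	8.8	8.1	7.5	6.7
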