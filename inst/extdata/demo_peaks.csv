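rt_min,mz
7.6,467.352
7.6,489.334
6.9,451.357
3.2,204.900
1.1,150.512
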