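((spA:1,spB:1):1,(spC:1.5,spD:0.5):2):0.5;
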