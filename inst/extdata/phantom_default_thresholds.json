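{"lumen":[600,1750],"intima":[1750,3750],"media":[3750,8000],"adventitia":[8000,10000]}
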