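sample_id,cg00001,cg00002,cg00003
bearA,0.12,0.50,0.88
bearB,0.20,0.45,0.91
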