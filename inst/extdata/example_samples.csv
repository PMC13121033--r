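sample_id,role,group
S1,labeled_mix,demo
S2,labeled_mix,demo
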