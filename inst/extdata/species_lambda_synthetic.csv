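species,lambda,gm_volume
mouse_like,0.77,112
marmoset_like,0.31,4000
macaque_like,0.19,55000
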