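name_a,delta_a,name_b,delta_b
rutin,12.650,beta-CD,9.658
rutin,12.650,HP-beta-CD,10.677
rutin,12.650,DM-beta-CD,12.422
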