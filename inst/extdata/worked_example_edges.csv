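pre,post,count
sen_pharyngeal_01,int_munin2,2000
sen_pharyngeal_02,int_munin2,1233
int_munin2,rpn_CRZ_1,2826
int_munin2,rpn_CRZ_2,2826
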