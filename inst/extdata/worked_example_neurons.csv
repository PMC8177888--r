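id,name,cell_class,cluster,sensory_origin,side
sen_pharyngeal_01,pharyngeal sensory 1,sensory,,pharyngeal,left
sen_pharyngeal_02,pharyngeal sensory 2,sensory,,pharyngeal,right
int_munin2,Munin 2,interneuron,Munin2,,left
rpn_CRZ_1,CRZ RPN 1,rpn,CRZ,,left
rpn_CRZ_2,CRZ RPN 2,rpn,CRZ,,right
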