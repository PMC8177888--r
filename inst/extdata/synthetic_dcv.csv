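# Synthetic example of a dense-core-vesicle fusion-site count table
# (per RPN group and ring gland tissue); not measured data.
rpn_group,tissue,fused_count
CRZ,CC_AO,9
CRZ,CA,2
CRZ,PG,1
IPCs,CC_AO,14
IPCs,CA,3
IPCs,PG,0
PTTH,PG,11
PTTH,CC_AO,1
PTTH,CA,0
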