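gene,protein_name,accession,peptide,charge,mz_light,mz_heavy
S100A8,calcium-binding protein A8,P05109,ALNSIIDVYHK,3,424.903,427.574
S100A8,calcium-binding protein A8,P05109,GADVWFK,2,411.710,415.718
S100A9,calcium-binding protein A9,P06702,DLYNFLK,2,456.744,460.752
LL-37,cathelicidin,P49913,LLGDFFR,2,434.239,439.243
DCD,dermcidin,P81605,ENAGEDPGLAR,2,564.767,569.771
hBD1,human beta-defensin 1,P60022,IQGTCYR,2,449.216,454.220
hBD2,human beta-defensin 2,O15263,GIGDPVTCLK,2,530.278,534.285
hBD3,human beta-defensin 3,P81534,GIINTLQK,2,443.771,447.778
hBD4,human beta-defensin 4,Q8WTQ1,ICGYGTAR,2,449.216,454.220
LACRT,lacritin,Q9GZZ8,QELNPLK,2,421.242,425.249
LACRT,lacritin,Q9GZZ8,SILLTEQALAK,2,593.855,597.862
LCN2,lipocalin-2,P80188,VPLQQNFQDNQFQGK,2,895.944,899.951
LCN2,lipocalin-2,P80188,SYNVTSVLFR,2,593.316,598.320
LCN2,lipocalin-2,P80188,TFVPGCQPGEFTLGNIK,2,932.966,936.973
LYZ,lysozyme,P61626,GISLANWMCLAK,2,682.346,686.353
LYZ,lysozyme,P61626,WESGYNTR,2,506.727,511.731
S100A7,psoriasin,P31151,SIIGMIDMFHK,2,646.330,650.337
TSLP,thymic stromal lymphopoietin,Q969D9,CLEQVSQLQGLWR,2,808.914,813.918
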