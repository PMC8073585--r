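p2,p1,p1prime,probability,note
W,K,P,0.90,WKP rescue of the proline block
M,R,P,0.90,MRP rescue of the proline block
.,K,P,0.05,proline at P1' blocks cleavage
.,R,P,0.05,proline at P1' blocks cleavage
C,K,D,0.20,acidic / bulky context damping
D,K,D,0.25,acidic context damping
C,K,H,0.20,context damping
C,K,Y,0.20,context damping
R,R,H,0.30,basic stacking damping
R,R,R,0.30,basic stacking damping
C,R,K,0.30,context damping
.,K,.,1.00,default lysine site
.,R,.,1.00,default arginine site
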