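atom,element,group,x,y,z
C14,C,ME7,3.237,-1.049,0.073
N7,N,RING5,2.220,-0.028,0.075
C8,C,NCH,2.432,1.324,0.131
N9,N,NCH,1.297,1.995,0.116
C4,C,RING5,0.336,1.033,0.049
C5,C,RING5,0.870,-0.219,0.022
C6,C,RING6,0.082,-1.401,-0.047
O6,O,OX6,0.574,-2.525,-0.071
N1,N,RING6,-1.290,-1.135,-0.084
C10,C,ME1,-2.202,-2.259,-0.156
C2,C,RING6,-1.881,0.146,-0.059
O2,O,OX2,-3.108,0.279,-0.096
N3,N,RING6,-1.021,1.243,0.010
C12,C,ME3,-1.549,2.595,0.040
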