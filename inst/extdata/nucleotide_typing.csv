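resname,atom,hb_donor,hb_acceptor,cation,anion,hydrophobe,halogen,ring
ANY,OP1,0,1,0,1,0,0,
ANY,O1P,0,1,0,1,0,0,
ANY,OP2,0,1,0,1,0,0,
ANY,O2P,0,1,0,1,0,0,
ANY,OP3,0,1,0,1,0,0,
ANY,O3P,0,1,0,1,0,0,
ANY,P,0,0,0,0,0,0,
ANY,O5',0,1,0,0,0,0,
ANY,O3',0,1,0,0,0,0,
ANY,O4',0,1,0,0,0,0,
ANY,O2',1,1,0,0,0,0,
A,N1,0,1,0,0,0,0,ring6
A,C2,0,0,0,0,0,0,ring6
A,N3,0,1,0,0,0,0,ring6
A,C4,0,0,0,0,0,0,ring6|ring5
A,C5,0,0,0,0,0,0,ring6|ring5
A,C6,0,0,0,0,0,0,ring6
A,N6,1,0,0,0,0,0,
A,N7,0,1,0,0,0,0,ring5
A,C8,0,0,0,0,0,0,ring5
A,N9,0,0,0,0,0,0,ring5
G,N1,1,0,0,0,0,0,ring6
G,C2,0,0,0,0,0,0,ring6
G,N2,1,0,0,0,0,0,
G,N3,0,1,0,0,0,0,ring6
G,C4,0,0,0,0,0,0,ring6|ring5
G,C5,0,0,0,0,0,0,ring6|ring5
G,C6,0,0,0,0,0,0,ring6
G,O6,0,1,0,0,0,0,
G,N7,0,1,0,0,0,0,ring5
G,C8,0,0,0,0,0,0,ring5
G,N9,0,0,0,0,0,0,ring5
C,N1,0,0,0,0,0,0,ring6
C,C2,0,0,0,0,0,0,ring6
C,O2,0,1,0,0,0,0,
C,N3,0,1,0,0,0,0,ring6
C,C4,0,0,0,0,0,0,ring6
C,N4,1,0,0,0,0,0,
C,C5,0,0,0,0,0,0,ring6
C,C6,0,0,0,0,0,0,ring6
U,N1,0,0,0,0,0,0,ring6
U,C2,0,0,0,0,0,0,ring6
U,O2,0,1,0,0,0,0,
U,N3,1,0,0,0,0,0,ring6
U,C4,0,0,0,0,0,0,ring6
U,O4,0,1,0,0,0,0,
U,C5,0,0,0,0,0,0,ring6
U,C6,0,0,0,0,0,0,ring6
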