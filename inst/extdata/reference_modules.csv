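group,module,label
middle,1,CACg(L)
middle,1,CACg(R)
middle,1,CMF(L)
middle,1,CMF(R)
middle,1,LOrF(L)
middle,1,PaC(L)
middle,1,Or(L)
middle,1,Tr(L)
middle,1,Tr(R)
middle,1,PreC(L)
middle,1,PreC(R)
middle,1,RoACg(R)
middle,1,FPol(R)
middle,1,Ins(L)
middle,1,MT(L)
middle,1,B(R)
middle,1,TPol(R)
middle,1,IP(L)
middle,1,PoCg(R)
middle,1,SP(R)
middle,1,Lg(L)
middle,1,PerCa(L)
middle,2,MOrF(L)
middle,2,SF(L)
middle,2,Or(R)
middle,2,Fu(L)
middle,2,En(R)
middle,2,MT(R)
middle,2,TrT(R)
middle,2,PoC(L)
middle,2,SM(L)
middle,2,IstCg(L)
middle,2,PoC(R)
middle,2,LO(L)
middle,2,LO(R)
middle,2,Cu(R)
middle,3,RoACg(L)
middle,3,FPol(L)
middle,3,PaC(R)
middle,3,Op(R)
middle,3,SF(R)
middle,3,En(L)
middle,3,TPol(L)
middle,3,TrT(L)
middle,3,PaH(R)
middle,3,ST(R)
middle,3,PoCg(L)
middle,3,IstCg(R)
middle,3,SM(R)
middle,4,Op(L)
middle,4,RoMF(L)
middle,4,RoMF(R)
middle,4,LOrF(R)
middle,4,IT(L)
middle,4,PaH(L)
middle,4,ST(L)
middle,4,Fu(R)
middle,4,IT(R)
middle,4,PreCu(L)
middle,4,Cu(L)
middle,5,MOrF(R)
middle,5,Ins(R)
middle,5,B(L)
middle,5,SP(L)
middle,5,IP(R)
middle,5,PreCu(R)
middle,5,Lg(R)
middle,5,PerCa(R)
elderly,1,Or(L)
elderly,1,RoACg(L)
elderly,1,RoACg(R)
elderly,1,RoMF(L)
elderly,1,Ins(L)
elderly,1,CMF(R)
elderly,1,LOrF(R)
elderly,1,PaC(R)
elderly,1,TPol(L)
elderly,1,MT(R)
elderly,1,ST(R)
elderly,1,PoC(L)
elderly,1,PreCu(L)
elderly,1,SP(L)
elderly,1,IstCg(R)
elderly,1,PreCu(R)
elderly,1,LO(L)
elderly,1,LO(R)
elderly,1,Lg(R)
elderly,2,CMF(L)
elderly,2,PreC(L)
elderly,2,PreC(R)
elderly,2,CACg(R)
elderly,2,Op(R)
elderly,2,Tr(R)
elderly,2,Fu(L)
elderly,2,PaH(L)
elderly,2,En(R)
elderly,2,Fu(R)
elderly,2,PaH(R)
elderly,2,TrT(R)
elderly,2,IstCg(L)
elderly,2,PoCg(L)
elderly,2,PoCg(R)
elderly,2,SM(R)
elderly,2,PerCa(L)
elderly,3,CACg(L)
elderly,3,LOrF(L)
elderly,3,MOrF(L)
elderly,3,PaC(L)
elderly,3,Op(L)
elderly,3,Tr(L)
elderly,3,SF(L)
elderly,3,RoMF(R)
elderly,3,Ins(R)
elderly,3,B(L)
elderly,3,MT(L)
elderly,3,ST(L)
elderly,3,SM(L)
elderly,3,PoC(R)
elderly,3,Cu(L)
elderly,3,Lg(L)
elderly,3,PerCa(R)
elderly,4,MOrF(R)
elderly,4,Or(R)
elderly,4,SF(R)
elderly,4,FPol(R)
elderly,4,En(L)
elderly,4,B(R)
elderly,4,IP(L)
elderly,4,Cu(R)
elderly,5,FPol(L)
elderly,5,IT(L)
elderly,5,IT(R)
elderly,5,TrT(L)
elderly,5,TPol(R)
elderly,5,SP(R)
elderly,5,IP(R)
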