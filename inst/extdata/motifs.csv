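motif_id,type,mz,tol,label,source
motif_505,frag,204.0866,0.01,N-acetylhexose oxocarbenium (A-B2 cleavage),literature
motif_668,frag,498.1817,0.01,HexNAc-pentose-hexose chain oxocarbenium (B1-C-D; C=pentose),literature
motif_451,frag,366.1395,0.01,HexNAc-hexose chain oxocarbenium (B1-C; C=hexose),computed
motif_451,frag,660.2346,0.01,pentose-HexNAc-hexose-hexose chain oxocarbenium (A-B1-C-D; C=hexose),computed
motif_437,frag,126.0550,0.01,tetramate heterocycle ion (C5-desmethyl; model-defined),model
motif_444,frag,140.0706,0.01,tetramate heterocycle ion (C5-methyl; model-defined),model
motif_660,frag,168.0655,0.01,tetramate core ion 1 (model-defined),model
motif_660,frag,182.0812,0.01,tetramate core ion 2 (model-defined),model
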