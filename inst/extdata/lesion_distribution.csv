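site,Benign,MoD,HiD,SCC
Buccal mucosa,11,1,1,9
Tongue,9,0,0,12
Lip,10,0,0,2
Gingiva,0,0,2,3
Floor of mouth,2,0,0,1
Mandible,0,0,0,1
Maxilla,0,0,0,1
Palate,1,0,0,0
Retromolar,1,0,0,0
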