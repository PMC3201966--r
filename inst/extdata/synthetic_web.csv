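"","sp001","sp002","sp003","sp004","sp005","sp006","sp007","sp008","sp009","sp010","sp011","sp012","sp013","sp014","sp015"
"sp001",1,0,0,1,0,0,1,0,0,0,0,0,0,0,0
"sp002",1,1,1,0,1,0,0,0,0,0,1,0,0,1,0
"sp003",0,0,1,0,0,1,0,0,0,0,0,0,0,0,0
"sp004",1,0,0,1,0,0,0,0,0,1,1,0,1,0,0
"sp005",0,1,0,0,0,0,0,0,0,0,0,0,0,0,0
"sp006",0,0,0,0,0,0,0,0,0,0,0,0,0,0,0
"sp007",1,1,0,1,0,0,1,0,0,0,0,0,0,0,0
"sp008",0,0,0,0,0,0,0,0,0,0,0,0,0,0,0
"sp009",0,0,1,1,0,1,0,0,0,0,0,0,0,0,0
"sp010",0,0,0,0,0,0,0,0,0,0,0,0,0,0,0
"sp011",0,1,0,0,0,0,0,0,0,0,0,0,0,0,0
"sp012",0,0,1,0,0,0,0,0,0,0,0,0,0,0,0
"sp013",0,1,0,0,0,0,0,0,0,0,1,0,0,0,0
"sp014",0,0,0,0,0,0,0,0,0,0,0,0,0,0,0
"sp015",0,0,0,0,0,0,0,0,0,0,0,0,0,0,0
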