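"parasite","stage_index","stage_role","transmission","hosts","source"
"par001",1,"definitive","direct","sp011;sp002;sp004","synthetic"
"par002",1,"intermediate","direct","sp003;sp006;sp002","synthetic"
"par002",2,"definitive","trophic","sp002;sp013;sp004","synthetic"
"par003",1,"intermediate","direct","sp003;sp001;sp002","synthetic"
"par003",2,"definitive","trophic","sp002;sp007;sp004","synthetic"
"par004",1,"definitive","direct","sp001;sp007;sp004","synthetic"
"par005",1,"definitive","direct","sp005;sp012;sp002","synthetic"
"par006",1,"intermediate","direct","sp011;sp001;sp003","synthetic"
"par006",2,"intermediate","trophic","sp013;sp004;sp002","synthetic"
"par006",3,"definitive","trophic","sp004;sp001;sp013","synthetic"
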