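name	old_Ma	young_Ma
Quaternary	2.58	0
Neogene	23.03	2.58
Paleogene	66.0	23.03
Cretaceous	145.0	66.0
Jurassic	201.4	145.0
Triassic	251.902	201.4
Permian	298.9	251.902
Carboniferous	358.9	298.9
Devonian	419.2	358.9
Silurian	443.8	419.2
Ordovician	485.4	443.8
Cambrian	538.8	485.4
Holocene	0.0117	0
Pleistocene	2.58	0.0117
Pliocene	5.333	2.58
Miocene	23.03	5.333
Oligocene	33.9	23.03
Eocene	56.0	33.9
Paleocene	66.0	56.0
Maastrichtian	72.1	66.0
Campanian	83.6	72.1
Santonian	86.3	83.6
Coniacian	89.8	86.3
Turonian	93.9	89.8
Cenomanian	100.5	93.9
Albian	113.0	100.5
Aptian	125.0	113.0
Barremian	129.4	125.0
Hauterivian	132.9	129.4
Valanginian	139.8	132.9
Berriasian	145.0	139.8
Tithonian	152.1	145.0
Kimmeridgian	157.3	152.1
Oxfordian	163.5	157.3
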