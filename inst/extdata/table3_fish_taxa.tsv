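order	family	genus	species	deep	mid	shallow	n_samples
Alepocephaliformes	Alepocephalidae	Alepocephalus	Alepocephalus agassizii	Y			1
Alepocephaliformes	Alepocephalidae	Alepocephalus		Y		Y	4
Alepocephaliformes	Alepocephalidae			Y		Y	2
Anguilliformes	Synaphobranchidae	Synaphobranchus		Y	Y		2
Argentiniformes	Bathylagidae	Bathylagus	Bathylagus euryops	Y	Y		2
Argentiniformes	Bathylagidae	Bathylagus		Y	Y		3
Argentiniformes	Bathylagidae			Y			1
Aulopiformes	Paralepididae	Paralepis	Paralepis coregonoides		Y		1
Beryciformes	Melamphaidae	Poromitra		Y	Y		2
Beryciformes	Melamphaidae				Y		1
Clupeiformes	Clupeidae			Y		Y	3
Gadiformes	Macrouridae	Coryphaenoides	Coryphaenoides rupestris		Y		1
Gadiformes	Macrouridae	Macrourus			Y		2
Gadiformes	Macrouridae			Y	Y	Y	12
Gadiformes	Moridae	Antimora	Antimora rostrata	Y		Y	4
Gadiformes	Moridae	Antimora		Y		Y	4
Myctophiformes	Myctophidae	Benthosema	Benthosema glaciale	Y	Y	Y	11
Myctophiformes	Myctophidae	Lampanyctus	Lampanyctus macdonaldi	Y	Y	Y	6
Myctophiformes	Myctophidae	Lampanyctus		Y	Y	Y	7
Myctophiformes	Myctophidae	Notoscopelus				Y	1
Myctophiformes	Myctophidae	Protomyctophum			Y	Y	5
Myctophiformes	Myctophidae			Y	Y	Y	41
Perciformes	Anarhichadidae	Anarhichas	Anarhichas denticulatus		Y		1
Perciformes	Anarhichadidae	Anarhichas			Y	Y	4
Perciformes	Anarhichadidae				Y	Y	2
Perciformes	Cottidae	Icelus			Y	Y	2
Perciformes	Liparidae	Psednos	Psednos groenlandicus	Y		Y	2
Perciformes	Liparidae	Psednos				Y	1
Perciformes	Pholidae	Pholis				Y	1
Perciformes	Pholidae					Y	2
Perciformes	Sebastidae	Sebastes	Sebastes mentella		Y		2
Perciformes	Sebastidae	Sebastes			Y		2
Perciformes	Zoarcidae					Y	2
Pleuronectiformes	Pleuronectidae	Reinhardtius	Reinhardtius hippoglossoides		Y		1
Pleuronectiformes	Pleuronectidae				Y		1
Rajiformes	Rajidae	Amblyraja		Y			2
Rajiformes	Rajidae	Rajella	Rajella bigelowi	Y			2
Rajiformes	Rajidae	Rajella		Y			2
Rajiformes	Rajidae			Y			2
Salmoniformes	Salmonidae				Y	Y	2
Stomiiformes	Gonostomatidae	Cyclothone	Cyclothone microdon	Y	Y	Y	6
Stomiiformes	Gonostomatidae	Cyclothone			Y	Y	9
Stomiiformes	Gonostomatidae				Y	Y	4
Stomiiformes	Stomiidae	Stomias	Stomias boa		Y	Y	2
Stomiiformes	Stomiidae	Stomias			Y	Y	2
Uranoscopiformes	Ammodytidae	Ammodytes	Ammodytes hexapterus			Y	1
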