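# edge_class=miR2gene	regulator	target
hsa-miR-901	G00093
hsa-miR-901	G00097
hsa-miR-901	G00038
hsa-miR-901	G00045
hsa-miR-901	G00111
hsa-miR-901	G00091
hsa-miR-901	G00108
hsa-miR-901	G00036
hsa-miR-901	G00048
hsa-miR-901	G00005
hsa-miR-901	G00031
hsa-miR-901	G00044
hsa-miR-901	G00058
hsa-miR-901	G00098
hsa-miR-901	G00088
hsa-miR-901	G00019
hsa-miR-901	G00079
hsa-miR-901	G00120
hsa-miR-901	G00010
hsa-miR-901	G00054
hsa-miR-901	G00018
hsa-miR-901	G00034
hsa-miR-901	G00103
hsa-miR-901	G00012
hsa-miR-901	G00056
hsa-miR-901	G00112
hsa-miR-901	G00035
hsa-miR-901	G00119
hsa-miR-901	G00003
hsa-miR-901	G00042
hsa-miR-901	TF01
hsa-miR-901	TF02
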