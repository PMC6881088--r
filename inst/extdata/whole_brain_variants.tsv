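site	count
Whole Brain	298
whole brain	266
Whole brain	189
WBRT	128
Brain	113
brain	21
wbxrt	8
WHOLE BRAIN	6
Whole brain 2	3
whole brain PCI	3
whole Brain	3
Whole Brain #2	3
Whole Brain PCI	3
Whole Brain Retreat	2
WHole Brain	2
whole brain 1	2
Whole Brain RT	2
WBRT (PCI)	2
whole brain-2	1
Whole Brain photons	1
PCI, whole brain	1
Whole brain/eyes/BOS	1
Whole Brain Proton	1
whole brain modulate	1
whole brain 2	1
Whole brain Primary	1
Whole Brain-PCI	1
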