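surface	expansion	cuis	semtypes
SCV	supraclavicular region	C0446461	T029
SCL	supraclavicular region	C0446461	T029
S/C	supraclavicular region	C0446461	T029
SC	supraclavicular region	C0446461	T029
S Clav	supraclavicular region	C0446461	T029
Sc V	supraclavicular region	C0446461	T029
Sclav	supraclavicular region	C0446461	T029
SCLV	supraclavicular region	C0446461	T029
WBRT	whole-brain radiotherapy	C1520143	T061
wbxrt	whole-brain radiotherapy	C1520143	T061
MLB	midline block		T169
Prox	Proximal	C0205107	T082
SV	Seminal Vesicle	C1278984	T023
PCI	prophylactic cranial irradiation		T061
RT	radiotherapy		T061
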