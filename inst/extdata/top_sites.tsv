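site	count	concepts
Pelvis	450	pelvis [C0030797,C0559769,C0030786,C1279864:T023,T029,T030]
SCV	428	supraclavicular region [C0446461:T029]
Whole Brain	298	whole [C0444667:T081];brain [C0006104,C1269537,C1882598,C1273723:T023,T029]
whole brain	266	whole [C0444667:T081];Brain [C0006104,C1269537,C1882598,C1273723:T023,T029]
Tumor Bed Boost	262	tumor [C0027651,C3273930,C1578706:T191,T170,T033];bed [C1547114:T082];Boost [C1511253:T169]
Left Breast	260	Left Breast [C0222601:T023]
Right Chest Wall	241	right [C0205090:T082];Chest wall [C0205076:T023]
Right Breast	239	Right Breast [C0222600:T023]
Left Chest Wall	206	Left [C0205091:T082];Chest wall [C0205076:T023]
pelvis	198	pelvis [C0030797,C0559769,C0030786,C1279864:T023,T029,T030]
Boost	194	Boost [C1511253:T169]
Whole brain	189	whole [C0444667:T081];Brain [C0006104,C1269537,C1882598,C1273723:T023,T029]
Prostate/Prox SV	159	Prostate [C0033572,C1278980,C1882832:T023];/ [PUNC:T000];Proximal [C0205107:T082];Seminal Vesicle [C1278984:T023]
boost	148	Boost [C1511253:T169]
SCV-MLB	147	supraclavicular region [C0446461:T029];midline block [:T169]
SCV MLB	139	supraclavicular region [C0446461:T029];midline block [:T169]
Right breast	134	Right Breast [C0222600:T023]
Prostate	129	Prostate [C0033572,C1278980,C1882832:T023]
WBRT	128	whole-brain radiotherapy [C1520143:T061]
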