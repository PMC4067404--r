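sample	n_raw	n_pass
Peripheral blood leukocytes	149896	137986
Bone marrow	171111	159515
Small intestine	118044	110313
Lung	198660	183264
Stomach	145163	133201
Lymph node	165091	157334
Tonsil	197846	186962
Spleen	185247	175689
Thymus	179969	168679
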