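name	sequence	orientation	specificity_class
Mod_RepCOI_F	TNTTYTCMACYAACCACAAAGA	F	vertebrate universal
Mod_RepCOI_R	TTCDGGRTGNCCRAARAATCA	R	universal
VertCOI_7194_F	CGMATRAAYAAYATRAGCTTCTGAY	F	vertebrate universal
VertCOI_7216_R	CARAAGCTYATGTTRTTYATDCG	R	vertebrate universal
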