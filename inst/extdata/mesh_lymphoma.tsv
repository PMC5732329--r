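D009369	Neoplasms	C04
D009370	Neoplasms by Histologic Type	C04.557
D006402	Hemic and Lymphatic Diseases	C15
D008206	Lymphatic Diseases	C15.604
D008232	Lymphoproliferative Disorders	C15.604.515;C20.683.515
D007154	Immune System Diseases	C20
D007160	Immunoproliferative Disorders	C20.683
D008223	Lymphoma	C04.557.386;C15.604.515.569;C20.683.515.761
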