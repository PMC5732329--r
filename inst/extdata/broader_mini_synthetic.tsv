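D007154	Immune System Diseases	C20
D007160	Immunoproliferative Disorders	C20.683
D008232	Lymphoproliferative Disorders	C20.683.515
D008223	Lymphoma	C20.683.515.761
D016393	Lymphoma, B-Cell	C20.683.515.761.480
D001260	Ataxia Telangiectasia	C20.673.480
D001402	B-Lymphocytes	A11
D006801	Humans	B01
D000818	Animals	B02
D018345	Mice, Knockout	B03
D016923	Cell Cycle Proteins	D05
D004268	DNA-Binding Proteins	D06
D017346	Protein-Serine-Threonine Kinases	D07
D064007	Ataxia Telangiectasia Mutated Proteins	D08
D019943	Cyclin D1	D09
D017404	In Situ Hybridization, Fluorescence	E01
D042822	Genomic Instability	G01
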