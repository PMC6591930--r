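entity_type	term
chemical	hydrocodone
chemical	acetaminophen
chemical	ibuprofen
chemical	tamoxifen
chemical	cisplatin
chemical	dopamine
chemical	glucose
chemical	ethanol
protein	hemoglobin
protein	insulin
protein	albumin
protein	cytochrome c
protein	trypsin
protein	ferritin
protein	collagen
protein	myosin
disease	asthma
disease	melanoma
disease	diabetes mellitus
disease	tuberculosis
disease	hypertension
disease	leukemia
disease	influenza
disease	hepatitis
organism	escherichia coli
organism	homo sapiens
organism	mus musculus
organism	saccharomyces cerevisiae
organism	drosophila melanogaster
organism	rattus norvegicus
anatomical_component	aorta
anatomical_component	hippocampus
anatomical_component	femur
anatomical_component	cornea
anatomical_component	pancreas
anatomical_component	cerebellum
cell_line_type	hela
cell_line_type	fibroblast
cell_line_type	lymphocyte
cell_line_type	hepatocyte
cell_line_type	keratinocyte
cell_line_type	macrophage
mutation	p.V600E
mutation	c.1521_1523delCTT
mutation	rs334
mutation	p.G12D
mutation	c.35G>T
mutation	p.R175H
gene	BRCA1
gene	TP53
gene	EGFR
gene	KRAS
gene	CFTR
gene	MYC
gene	APOE
subcellular_structure	mitochondrion
subcellular_structure	ribosome
subcellular_structure	nucleolus
subcellular_structure	lysosome
subcellular_structure	endoplasmic reticulum
subcellular_structure	golgi apparatus
tissue_organ	liver
tissue_organ	kidney
tissue_organ	myocardium
tissue_organ	epidermis
tissue_organ	lung
tissue_organ	spleen
mirna	mir-21
mirna	mir-155
mirna	let-7a
mirna	mir-34a
mirna	mir-200c
mirna	mir-146b
go	apoptotic process
go	signal transduction
go	dna repair
go	cell cycle arrest
go	protein folding
go	oxidative phosphorylation
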