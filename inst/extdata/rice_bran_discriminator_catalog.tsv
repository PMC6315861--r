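metabolite	chemical_class	pathway
quinate	amino acids	aromatic amino acids (PEP-derived)
serotonin	amino acids	aromatic amino acids (PEP-derived)
tryptophan	amino acids	aromatic amino acids (PEP-derived)
tyrosine	amino acids	aromatic amino acids (PEP-derived)
lysine	amino acids	aspartate family (OAA-derived)
N6,N6,N6-trimethyllysine	amino acids	aspartate family (OAA-derived)
threonine	amino acids	aspartate family (OAA-derived)
asparagine	amino acids	aspartate family (OAA-derived)
aspartate	amino acids	aspartate family (OAA-derived)
methionine sulfoxide	amino acids	aspartate family (OAA-derived)
pipecolate	amino acids	aspartate family (OAA-derived)
arginine	amino acids	glutamate family (alpha-ketoglutarate-derived)
glutamate	amino acids	glutamate family (alpha-ketoglutarate-derived)
glutamine	amino acids	glutamate family (alpha-ketoglutarate-derived)
N-acetylglutamate	amino acids	glutamate family (alpha-ketoglutarate-derived)
pyroglutamine	amino acids	glutamate family (alpha-ketoglutarate-derived)
N-methylproline	amino acids	glutamate family (alpha-ketoglutarate-derived)
stachydrine	amino acids	glutamate family (alpha-ketoglutarate-derived)
trans-4-hydroxyproline	amino acids	glutamate family (alpha-ketoglutarate-derived)
glycine	amino acids	serine family (phosphoglycerate-derived)
taurine	amino acids	serine family (phosphoglycerate-derived)
arabonate/xylonate	carbohydrates	amino sugars and nucleotide sugars
ribonate	carbohydrates	amino sugars and nucleotide sugars
glucosaminate	carbohydrates	amino sugars and nucleotide sugars
erythritol	carbohydrates	amino sugars and nucleotide sugars
aconitate	carbohydrates	TCA cycle
alpha-ketoglutarate	carbohydrates	TCA cycle
malate	carbohydrates	TCA cycle
gamma-tocopherol/beta-tocopherol	cofactors & vitamins	tocopherol metabolism
gamma-tocotrienol	cofactors & vitamins	tocopherol metabolism
laurate	lipids	free fatty acids
linoleate	lipids	free fatty acids
linolenate	lipids	free fatty acids
myristate	lipids	free fatty acids
myristoleate	lipids	free fatty acids
palmitate	lipids	free fatty acids
palmitoleate	lipids	free fatty acids
diacylglycerol (14:0/18:1, 16:0/16:1)	lipids	glycerolipids (diacyl)
linoleoyl-linolenoyl-glycerol (18:2/18:3) [1]	lipids	glycerolipids (diacyl)
linoleoyl-linolenoyl-glycerol (18:2/18:3) [2]	lipids	glycerolipids (diacyl)
linoleoyl-linoleoyl-glycerol (18:2/18:2)	lipids	glycerolipids (diacyl)
oleoyl-linoleoyl-glycerol (18:1/18:2) [1]	lipids	glycerolipids (diacyl)
oleoyl-linoleoyl-glycerol (18:1/18:2) [2]	lipids	glycerolipids (diacyl)
oleoyl-oleoyl-glycerol (18:1/18:1) [1]	lipids	glycerolipids (diacyl)
oleoyl-oleoyl-glycerol (18:1/18:1) [2]	lipids	glycerolipids (diacyl)
palmitoleoyl-linoleoyl-glycerol (16:1/18:2)	lipids	glycerolipids (diacyl)
palmitoyl-linoleoyl-glycerol (16:0/18:2) [1]	lipids	glycerolipids (diacyl)
palmitoyl-linoleoyl-glycerol (16:0/18:2) [2]	lipids	glycerolipids (diacyl)
palmitoyl-oleoyl-glycerol (16:0/18:1)	lipids	glycerolipids (diacyl)
palmitoyl-palmitoyl-glycerol (16:0/16:0) [1]	lipids	glycerolipids (diacyl)
palmitoyl-palmitoyl-glycerol (16:0/16:0) [2]	lipids	glycerolipids (diacyl)
1-linoleoylglycerol (18:2)	lipids	glycerolipids (monoacyl)
1-oleoylglycerol (18:1)	lipids	glycerolipids (monoacyl)
1-palmitoylglycerol (16:0)	lipids	glycerolipids (monoacyl)
2-oleoylglycerol (18:1)	lipids	glycerolipids (monoacyl)
1-linoleoyl-GPE (18:2)	lipids	lyso-phospholipids
1-palmitoyl-GPC (16:0)	lipids	lyso-phospholipids
1-palmitoyl-GPE (16:0)	lipids	lyso-phospholipids
12,13-DiHOME	lipids	oxylipins
9,10-DiHOME	lipids	oxylipins
9,10-epoxystearate	lipids	oxylipins
glycerophosphoglycerol	lipids	phospholipid metabolism
glycerophosphorylcholine	lipids	phospholipid metabolism
guanine	nucleotides	purine metabolism
hypoxanthine	nucleotides	purine metabolism
adenosine	nucleotides	purine metabolism
1-methyladenine	nucleotides	purine metabolism
adenosine 5'-monophosphate	nucleotides	purine metabolism
adenine	nucleotides	purine metabolism
4-hydroxybenzoate	secondary metabolites	benzenoids
salicylate	secondary metabolites	benzenoids
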