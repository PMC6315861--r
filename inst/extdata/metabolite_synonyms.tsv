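synonym	canonical
l-quinate	quinate
alpha-linolenate	linolenate
cis-aconitate	aconitate
alpha-ketoglutarate (2-oxoglutarate)	alpha-ketoglutarate
2-oxoglutarate	alpha-ketoglutarate
glycerophosphorylcholin (sn-glycero-3-phosphocholine)	glycerophosphorylcholine
sn-glycero-3-phosphocholine	glycerophosphorylcholine
glycerophosphorylcholin	glycerophosphorylcholine
GPC	glycerophosphorylcholine
beta-tocopherol	gamma-tocopherol/beta-tocopherol
gamma-tocopherol	gamma-tocopherol/beta-tocopherol
adenosine 5'-monophosphate (AMP)	adenosine 5'-monophosphate
AMP	adenosine 5'-monophosphate
glucosamine	glucosaminate
1-linoleoyl-glycerophosphoethanolamine (18:2)	1-linoleoyl-GPE (18:2)
1-palmitoyl-glycerophosphocholine (16:0)	1-palmitoyl-GPC (16:0)
1-palmitoyl-glycerophosphoethanolamine (16:0)	1-palmitoyl-GPE (16:0)
12,13-dihydroxyoctadec-9-enoic acid	12,13-DiHOME
12,13-dihydroxyoctadec-9-enoic acid (12,13-DiHOME)	12,13-DiHOME
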