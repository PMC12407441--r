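metabolite	heatmap_cluster	category
1-(1-enyl-palmitoyl)-2-oleoyl-GPC	Enriched_WT	Genotype
2-aminobutyrate	Enriched_CTL	Diet
2'-deoxycytidine	Enriched_WT	Genotype
3-hydroxybutyrate	Enriched_WT	Genotype
adenine	Enriched_Tg	Genotype
caprate	Enriched_HF	Diet
cysteine	Enriched_WT	Genotype
histidine	Enriched_Tg	Genotype
laurate	Enriched_WT	Genotype
linoleyl-arachidonoyl-glycerol	Enriched_CTL	Diet
linoleyl-linoleoyl-glycero	Enriched_CTL	Diet
margarate	Enriched_HF	Diet
methylpalmitate	Enriched_HF	Diet
myristate	Enriched_HF	Diet
myristoylcarnitine	Enriched_Tg	Genotype
palmitate	Enriched_HF	Diet
sphingomyelin	Enriched_Tg	Genotype
uridine	Enriched_WT	Genotype
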