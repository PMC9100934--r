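# Genera characteristic for the human gut microbiota (user-editable).
# One genus per line; lines starting with '#' are ignored.
Bacteroides
Prevotella 9
Prevotella 7
Prevotella 2
Faecalibacterium
Alistipes
Parabacteroides
Blautia
Roseburia
Ruminococcus 1
Ruminococcus 2
Agathobacter
Anaerostipes
Bifidobacterium
Collinsella
Coprococcus 1
Coprococcus 2
Coprococcus 3
Dorea
Dialister
Eubacterium
Lachnoclostridium
Lachnospira
Oscillibacter
Phascolarctobacterium
Subdoligranulum
Sutterella
Akkermansia
Butyricicoccus
Butyricimonas
Christensenellaceae R-7 group
Clostridium sensu stricto 1
Desulfovibrio
Bilophila
Escherichia-Shigella
Fusicatenibacter
Haemophilus
Holdemanella
Intestinibacter
Lactobacillus
Megamonas
Megasphaera
Odoribacter
Parasutterella
Peptococcus
Romboutsia
Streptococcus
Terrisporobacter
Tyzzerella
Veillonella
Victivallis
Barnesiella
Butyrivibrio
Catenibacterium
Enterococcus
Flavonifractor
Hungatella
Marvinbryantia
Mitsuokella
Slackia
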