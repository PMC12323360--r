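taxon	level	category	citation
Escherichia	genus	aerotolerant	Enterobacteriaceae; facultative anaerobe counted as aerotolerant
Shigella	genus	aerotolerant	Enterobacteriaceae; facultative anaerobe counted as aerotolerant
Klebsiella	genus	aerotolerant	Enterobacteriaceae; facultative anaerobe counted as aerotolerant
Enterobacter	genus	aerotolerant	Enterobacteriaceae; facultative anaerobe counted as aerotolerant
Citrobacter	genus	aerotolerant	Enterobacteriaceae; facultative anaerobe counted as aerotolerant
Proteus	genus	aerotolerant	Enterobacteriaceae; facultative anaerobe counted as aerotolerant
Salmonella	genus	aerotolerant	Enterobacteriaceae; facultative anaerobe counted as aerotolerant
Serratia	genus	aerotolerant	Enterobacteriaceae; facultative anaerobe counted as aerotolerant
Lactobacillus	genus	aerotolerant	aerotolerant fermenter
Streptococcus	genus	aerotolerant	facultative anaerobe counted as aerotolerant
Enterococcus	genus	aerotolerant	facultative anaerobe counted as aerotolerant
Staphylococcus	genus	aerotolerant	facultative anaerobe counted as aerotolerant
Bacillus	genus	aerotolerant	aerobe/facultative
Pseudomonas	genus	aerotolerant	aerobe
Haemophilus	genus	aerotolerant	facultative anaerobe counted as aerotolerant
Bacteroides	genus	strict_anaerobe	obligate anaerobe
Prevotella	genus	strict_anaerobe	obligate anaerobe
Faecalibacterium	genus	strict_anaerobe	obligate anaerobe
Roseburia	genus	strict_anaerobe	obligate anaerobe
Ruminococcus	genus	strict_anaerobe	obligate anaerobe
Akkermansia	genus	strict_anaerobe	obligate anaerobe
Christensenella	genus	strict_anaerobe	obligate anaerobe
Methanobrevibacter	genus	strict_anaerobe	obligate anaerobic archaeon
Blautia	genus	strict_anaerobe	obligate anaerobe
Coprococcus	genus	strict_anaerobe	obligate anaerobe
Dorea	genus	strict_anaerobe	obligate anaerobe
Alistipes	genus	strict_anaerobe	obligate anaerobe
Parabacteroides	genus	strict_anaerobe	obligate anaerobe
Clostridium	genus	strict_anaerobe	obligate anaerobe
Eubacterium	genus	strict_anaerobe	obligate anaerobe
Dialister	genus	strict_anaerobe	obligate anaerobe
Veillonella	genus	strict_anaerobe	obligate anaerobe
Bifidobacterium longum	species	strict_anaerobe	Bifidobacterium handled at species level
Bifidobacterium adolescentis	species	strict_anaerobe	Bifidobacterium handled at species level
Bifidobacterium bifidum	species	strict_anaerobe	Bifidobacterium handled at species level
Bifidobacterium breve	species	strict_anaerobe	Bifidobacterium handled at species level
Bifidobacterium pseudocatenulatum	species	strict_anaerobe	Bifidobacterium handled at species level
Bifidobacterium animalis	species	aerotolerant	oxygen-tolerant Bifidobacterium; species-level call
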