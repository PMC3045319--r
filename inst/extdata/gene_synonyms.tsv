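# Local (gene, organism) -> additional gene name table used by the
# additional-gene-name feature in place of live protein-database lookups.
# gene <TAB> organism <TAB> additional_name
IL2	mouse	Interleukin
Il2	mouse	Interleukin
Copg1	mouse	gamma-COP
Copg2	mouse	gamma-COP
Adh	fly	Alcohol-dehydrogenase
w	fly	white
CDC28	yeast	Cyclin-dependent-kinase
GAL4	yeast	Galactose-regulon
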