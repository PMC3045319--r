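# Default organism lexicon: surface form <TAB> canonical label.
# Matching is case-insensitive; multi-token surfaces match as one mention.
fly	fly
flies	fly
drosophila	fly
drosophila melanogaster	fly
d. melanogaster	fly
d melanogaster	fly
fruit fly	fly
mouse	mouse
mice	mouse
murine	mouse
mus musculus	mouse
m. musculus	mouse
yeast	yeast
yeasts	yeast
saccharomyces	yeast
saccharomyces cerevisiae	yeast
s. cerevisiae	yeast
budding yeast	yeast
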