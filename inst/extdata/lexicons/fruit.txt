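# Fruit terms (whole fruits and purees). Matching is case-insensitive on
# whole words with light plural folding ("strawberries" matches
# "strawberry"). Exclusions in fruit_exclude.txt are applied first, so
# "apple puree concentrate" or "strawberry jam" never count.
apple
apricot
banana
blackberry
blackcurrant
blueberry
cherry
clementine
cranberry
currant
date
fig
fruit puree
grape
grapefruit
guava
kiwi
lemon
lime
mandarin
mango
melon
nectarine
orange
papaya
passion fruit
peach
pear
pineapple
plum
pomegranate
prune
raisin
raspberry
strawberry
tangerine
watermelon
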