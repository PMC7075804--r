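# Fruit exclusions, checked before the fruit list. Concentrated fruit
# juices (used as sweeteners), jams, pectins, flavors, powders and fruit
# leathers do not count as fruit.
concentrate
concentrated
jam
pectin
flavor
flavour
flavoring
flavouring
powder
leather
extract
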