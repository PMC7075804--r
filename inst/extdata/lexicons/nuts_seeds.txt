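# Nut and seed terms for FVN detection; peanuts and seeds count toward FVN.
# Legumes other than peanuts are not included by default.
almond
brazil nut
cashew
chia
flax seed
flaxseed
hazelnut
macadamia
peanut
pecan
pine nut
pistachio
poppy seed
pumpkin seed
sesame
sunflower seed
walnut
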