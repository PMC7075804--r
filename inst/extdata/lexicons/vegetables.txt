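# Vegetable terms for FVN detection. Starchy vegetables (potato, corn) are
# deliberately absent: in chip form they never qualify, and the shipped
# default excludes them everywhere (conservative). Adding "potato" or
# "corn" here still leaves them excluded for products in the chip
# categories (WWEIA 5002/5004/5008).
beet
beetroot
broccoli
carrot
cauliflower
celery
cucumber
kale
pea
pepper
pumpkin
spinach
squash
tomato
zucchini
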