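# Dairy terms counted by the dairy-first rule.
# The rule enumerates milk, yogurt, and cheese only. Matching is on whole
# words within a token name, so qualified variants ("whole milk",
# "skim milk", "low fat milk", "greek yogurt", "cheddar cheese") match
# through their head noun. NOTE: "cream" is deliberately absent — the rule
# sentence lists only milk, yogurt and cheese, so cream-first products
# (e.g. premium ice creams) do not classify as dairy-first.
milk
yogurt
yoghurt
cheese
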