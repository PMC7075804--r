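# Dairy exclusions, checked before the inclusion list. Milk chocolate,
# milk powders and milk solids do not qualify as dairy wherever they occur.
# Multi-word phrases match as consecutive whole words, so "skim milk powder"
# is excluded via "milk powder" and "modified/dehydrated milk solids" via
# "milk solids".
milk chocolate
milk powder
milk solids
milk protein concentrate
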