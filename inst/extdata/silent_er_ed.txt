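# Words ending in "er" or "ed" whose ending is pronounced like a closed "e"
# in French (infinitives and a few nouns). One word per line; members must
# end in "er" or "ed". The packaged list is a small starter lexicon; supply
# a fuller one for production use.
aller
parler
manger
fumer
soigner
saigner
avaler
respirer
vacciner
operer
accoucher
marcher
uriner
masser
ausculter
transpirer
pied
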