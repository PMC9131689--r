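# dietary supplements
dietary supplement
vitamin
vitamin e
vitamin d
omega 3
fish oil
coenzyme q10
creatine
curcumin
nutritional drink
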