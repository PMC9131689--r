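# phrases marking pharmacological interventions (dose forms and a few
# canonical agents); the registry's declared type usually decides, this list
# catches undeclared drug names
oral tablet
oral capsule
oral solution
intravenous infusion
subcutaneous injection
hydrochloride
tartrate
mesylate
levodopa
donepezil
rivastigmine
memantine hydrochloride
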