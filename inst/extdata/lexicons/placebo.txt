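# placebo / vehicle-control interventions (removed before basket counting)
placebo
matching placebo
sugar pill
vehicle control
saline
sham
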