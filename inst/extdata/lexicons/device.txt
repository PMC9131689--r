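# device interventions
device
deep brain stimulation
transcranial magnetic stimulation
transcranial direct current stimulation
vagus nerve stimulation
neurostimulation
spinal cord stimulation
electrode implant
infusion pump
focused ultrasound
hearing aid
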