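# biomarker / measurement-only interventions
biomarker
positron emission tomography
pet imaging
pet scan
radiotracer
florbetapir
flortaucipir
lumbar puncture
cerebrospinal fluid sampling
magnetic resonance imaging
blood sampling
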