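# interventions outside the drug/device/behavioral taxonomy
radiation
surgery
surgical procedure
genetic testing
questionnaire
survey
standard of care
usual care
diagnostic test
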