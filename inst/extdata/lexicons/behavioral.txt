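# behavioral / lifestyle interventions
behavioral therapy
cognitive behavioral therapy
cognitive training
physical therapy
physical exercise
exercise program
aerobic exercise
speech therapy
occupational therapy
music therapy
mindfulness
meditation
counseling
psychoeducation
caregiver education
rehabilitation
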