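study
survey
investigation
experiment
experimentation
trial
examination
inquiry
enquiry
research
review
audit
evaluation
assessment
screening
exploration
probe
inspection
scrutiny
workup
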