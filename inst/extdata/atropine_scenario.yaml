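# In-silico vagal-blockade scenario: 7 subjects, atropine at 750 s.
# Fields mirror the arguments of fsindex::scenario_config().
drug: atropine
n_subjects: 7
duration: 1500
drug_time: 750
basal_hr: 156
seed: 1
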