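sample_id,well_id,accepted,mut_positive,wt_positive,input_mass_ng
brain_validation,A01,11000,90,9600,75.5
brain_validation,A02,11000,88,9650,75.5
blood_validation,B01,11200,0,9800,83.5
blood_validation,B02,11150,1,9750,83.5
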