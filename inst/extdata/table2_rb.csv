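compound,rb_exp_mean,rb_exp_sd,rb_acid_base,rb_mechanistic
Intermedine,1.12,0.0853,1.00,0.807
Intermedine N-oxide,0.689,0.0499,1.00,0.867
Lasiocarpine,0.736,0.0438,1.00,0.601
Lasiocarpine N-oxide,0.897,0.0718,1.00,0.605
Monocrotaline,1.07,0.0865,1.00,0.672
Monocrotaline N-oxide,0.709,0.0430,1.00,0.674
Retrorsine,1.08,0.0859,1.00,0.717
Retrorsine N-oxide,0.736,0.228,1.00,0.830
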