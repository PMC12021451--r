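compound,fu_p
Intermedine,0.890
Intermedine N-oxide,1.08
Lasiocarpine,0.227
Lasiocarpine N-oxide,0.237
Monocrotaline,0.456
Monocrotaline N-oxide,0.461
Retrorsine,0.600
Retrorsine N-oxide,0.960
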