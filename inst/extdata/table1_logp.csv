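compound,logp_exp_mean,logp_exp_sd,kowwin,clogp,sparc,splogp
Intermedine,-1.93,0.168,0.91,-0.96,-0.85,-0.045
Intermedine N-oxide,-1.36,0.0346,0.15,,,-0.875
Lasiocarpine,-0.487,0.0220,2.43,0.65,1.21,1.59
Lasiocarpine N-oxide,-0.302,0.0269,1.66,0.77,,0.319
Monocrotaline,-1.92,0.0727,-1.18,-0.93,-1.01,-0.686
Monocrotaline N-oxide,-1.61,0.0352,-1.95,,,-1.56
Retrorsine,-1.26,0.0610,-0.25,-0.62,-0.24,-0.298
Retrorsine N-oxide,-1.24,0.0421,-1.01,-0.50,,-1.26
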