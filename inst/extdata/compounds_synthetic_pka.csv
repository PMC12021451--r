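name,compound_class,ester_type,acid_base,pka
Intermedine,PA,monoester,base,6.0
Intermedine N-oxide,PANO,monoester,base,4.0
Lasiocarpine,PA,open_chained_diester,base,6.0
Lasiocarpine N-oxide,PANO,open_chained_diester,base,4.0
Monocrotaline,PA,cyclic_diester,base,6.0
Monocrotaline N-oxide,PANO,cyclic_diester,base,4.0
Retrorsine,PA,cyclic_diester,base,6.0
Retrorsine N-oxide,PANO,cyclic_diester,base,4.0
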