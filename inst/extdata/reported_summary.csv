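name,value
screens_cms,988000000
screens_cng,1430000000
life_years_cms,5798331
life_years_cng,6623148
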