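id	sp_start	sp_end	a1_start	a1_end	a2_start	a2_end	a3_start	a3_end	tm_start	tm_end	ct_start	ct_end
REF01	1	24	25	114	115	206	207	298	309	331	332	359
REF02	1	24	25	114	115	206	207	298	309	331	332	361
REF03	1	24	25	114	115	206	207	298	309	331	332	359
REF04	1	24	25	114	115	206	207	298	309	331	332	364
REF05	1	24	25	114	115	206	207	298	309	331	332	343
REF06	1	24	25	114	115	206	207	298	309	331	332	359
REF07	1	24	25	114	115	206	207	298	309	331	332	361
REF08	1	24	25	114	115	206	207	298	309	331	332	357
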