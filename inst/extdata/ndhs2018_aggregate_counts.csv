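covariate,level,n,n_overweight
all,all,13339,3628
residence,urban,5611,1994
residence,rural,7728,1634
contraceptive,user,11080,2638
contraceptive,none_user,2259,990
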