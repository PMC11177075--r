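group,N,P,n_ge1,n_ge2,n_eq3,pos_ge1,pos_ge2,pos_eq3
G2005,162710,1161,75236,16633,2705,1004,666,258
G2010,186228,1420,80617,16290,2315,1266,811,309
G2015,190794,1801,81144,15978,2364,1614,1029,396
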