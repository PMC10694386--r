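threat,code,max_dist_km,weight,decay
Paddy field,1,6,0.6,exponential
Dry land,2,6,0.6,exponential
Urban land,7,10,0.9,exponential
Rural residential land,9,8,0.7,exponential
Industrial and traffic land,10,12,1,linear
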