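lucode,name,habitat,Paddy field,Dry land,Urban land,Rural residential land,Industrial and traffic land
1,Paddy,0.3,0,0.2,0.6,0.4,0.5
2,Dry land,0.3,0.2,0,0.6,0.4,0.5
3,Forestland,1,0.8,0.8,0.9,0.8,0.9
4,Shrubland,0.9,0.5,0.5,0.8,0.7,0.8
5,Grassland,0.8,0.5,0.5,0.6,0.5,0.6
6,Water body,1,0.8,0.7,0.9,0.8,0.9
7,Urban,0,0,0,0,0,0
8,Bare land,0.1,0.1,0.1,0.2,0.2,0.1
9,Rural residential land,0,0,0,0,0,0
10,Industrial and traffic land,0,0,0,0,0,0
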