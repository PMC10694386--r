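class,Arable land,Woodland,Shrubs,Grassland,Water area,Bare ground,Building sites,Total
Arable land,11860.1,495.88,0,3.7,169.4,0.2,0.02,12529.3
Woodland,418.3,6394.5,0,0.6,3.0,0,0.03,6816.4
Shrubs,0.1,0.2,0.1,0.02,0,0,0.03,0.5
Grassland,2.8,0.2,0,7.6,4.6,4.4,0.04,19.6
Water area,692.6,24.3,0,1.4,3332.8,2.1,0.05,4053.3
Bare ground,0.4,0,0,1.7,4.0,8.5,0.07,14.8
Building sites,1.1,0,0,0.01,15.9,0,0.08,17.1
Total,12975.3,6915.1,0.1,15.2,3529.8,15.2,0.32,23451
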