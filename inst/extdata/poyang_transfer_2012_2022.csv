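class,Arable land,Woodland,Shrubs,Grassland,Water area,Bare ground,Building sites,Total
Arable land,7568.3,1264.3,0.1,402.8,1325.8,14.6,2219.9,12795.7
Woodland,254.0,6336.4,0.1,96.5,86.8,6.0,104.1,6883.7
Shrubs,0,0.1,0,0.1,0,0,0,0.1
Grassland,2.1,0.41,0,4.9,3.0,2.3,2.4,15.1
Water area,88.9,2.71,0,37.3,3314.7,16.7,33.0,3493.3
Bare ground,0.2,0.11,0,6.3,3.0,5.3,0.2,15.1
Building sites,108.4,30.2,0,45.8,93.7,11.3,974.0,1263.3
Total,8021.8,7634.1,0.2,593.6,4827.0,56.1,3333.6,24466.3
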