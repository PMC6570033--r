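sample_id,location,sand,silt,clay,cec,area,whc,ph,total_c,ignition_loss,soil_type
S-1,Toyama,87.8,7.5,4.7,1.7,14,23,7.08,0.02,0.6,sandy
S-2,Shizuoka,95.0,1.2,3.7,0.6,23,43,6.32,0.10,0.3,sandy
S-3,Gifu,63.3,15.5,10.1,4.0,33,31,5.69,2.09,10.1,sandy
S-4,Nagano,92.9,5.0,2.1,1.9,31,27,6.20,0.01,1.2,sandy
S-5,Yamaguchi,99.9,0.1,0.0,0.5,28,28,6.60,0.00,0.4,sandy
A-1,Shizuoka,12.6,39.1,48.3,37.9,51,94,4.09,8.20,19.7,andosol
A-2,Kanto region,17.2,58.7,24.0,33.1,65,78,5.65,5.70,18.9,andosol
A-3,Gunma,44.1,50.2,5.7,42.0,83,86,5.60,6.46,17.4,andosol
A-4,Nagano,16.9,51.7,31.4,27.8,85,84,5.54,6.44,16.1,andosol
B-1,Aichi,42.6,20.6,36.8,7.6,40,48,4.06,0.52,5.9,brown_forest
B-2,Fukushima,17.2,25.7,57.1,13.2,55,55,4.70,1.20,9.5,brown_forest
B-3,Aichi,41.6,30.3,28.1,10.5,53,50,5.54,0.34,3.9,brown_forest
C-1,Shiga,42.7,21.2,36.1,17.7,34,54,5.43,1.81,5.9,cohesive
C-2,Saitama,8.6,50.4,41.1,15.5,55,52,6.10,0.70,5.6,cohesive
C-3,Nagano,40.9,39.8,19.3,10.9,62,60,5.66,2.70,6.8,cohesive
C-4,Aichi,6.8,54.2,39.0,32.2,81,81,5.54,4.22,12.4,cohesive
O-1,(OECD soil),70.0,15.2,14.8,8.7,,55,5.90,6.85,6.6,cohesive
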