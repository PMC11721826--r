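cluster,name,cases_exposed,controls_exposed,printed_p,printed_or,printed_or_dp,degree
D64,Other anaemias,8,7,0.016,3.51,2,1
H16/H60,Keratitis; otitis externa,60,130,0.017,1.6,1,5
J41/J45,Chronic bronchitis; asthma,129,336,0.017,1.65,2,5
L01/L24,Impetigo; irritant contact dermatitis,79,185,0.022,1.53,2,5
M00,Pyogenic arthritis,3,0,0.015,21.34,2,3
M41/M54,Scoliosis; dorsalgia,11,5,<0.001,6.63,2,4
M62/M65/M67,Disorders of muscle and synovium/tendon,54,22,<0.001,10.23,2,7
Q65,Congenital deformities of hip,4,0,0.004,27.61,2,3
Q66,Congenital deformities of feet,3,0,0.015,21.34,2,1
S30/S33/S70/S73,"Injuries of abdomen, lower back, pelvis and hip",32,25,<0.001,4.48,2,6
S50/S80/S83/T00,Injuries of limbs and multiple regions,42,48,<0.001,3.17,2,7
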