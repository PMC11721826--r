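cluster,name,cases_exposed,controls_exposed,printed_p,printed_or,printed_or_dp,degree
D64,Other anaemias,8,7,0.016,3.51,2,3
H16,Keratitis,30,59,0.048,1.65,2,4
H60,Otitis externa,43,85,0.017,1.7,1,4
J41,Simple and mucopurulent chronic bronchitis,17,22,0.012,2.48,2,4
J45,Asthma,124,330,0.045,1.49,2,4
L01,Impetigo,62,139,0.025,1.54,2,8
L24,Irritant contact dermatitis,40,76,0.013,1.77,2,5
M00,Pyogenic arthritis,3,0,0.015,21.34,2,4
M41,Scoliosis,4,1,0.015,9.18,2,5
M54,Dorsalgia,7,4,0.007,5.17,2,7
M62,Other disorders of muscle,7,4,0.007,5.17,2,6
M65,Synovitis and tenosynovitis,15,8,<0.001,5.9,1,5
M67,Other disorders of synovium and tendon,40,12,<0.001,12.44,2,9
Q65,Congenital deformities of hip,4,0,0.004,27.61,2,2
Q66,Congenital deformities of feet,3,0,0.015,21.34,2,1
S30,"Superficial injury of abdomen, lower back and pelvis",5,4,0.048,3.74,2,6
S33,"Dislocation, sprain and strain of joints and ligaments of lumbar spine and pelvis",15,11,<0.001,4.34,2,11
S50,Superficial injury of forearm,10,12,0.041,2.61,2,2
S70,Superficial injury of hip and thigh,10,7,0.003,4.4,1,8
S73,"Dislocation, sprain and strain of joint and ligaments of hip",16,10,<0.001,5.1,1,6
S80,Superficial injury of lower leg,16,19,0.008,2.7,1,10
S83,"Dislocation, sprain and strain of joints and ligaments of knee",16,15,0.001,3.42,2,10
T00,Superficial injuries involving multiple body regions,8,7,0.016,3.51,2,1
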