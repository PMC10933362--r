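cultivar,part,ci_low,ci_high,centroid
Caeté,N,2.859,2.935,30.7
Caeté,P,0.854,1.008,4.3
Caeté,K,2.685,2.749,25.7
Caeté,Ca,1.748,1.813,10.1
Caeté,Mg,0.644,0.712,3.3
Caeté,S,1.449,1.575,7.7
Caeté,B,-3.859,-3.726,0.038
Caeté,Cu,-3.951,-3.850,0.034
Caeté,Zn,-3.332,-3.241,0.063
Caeté,Mn,-2.794,-2.366,0.129
Caeté,Fe,-3.364,-3.138,0.066
Caeté,Fv,6.259,6.329,917.9
Mulata,N,3.334,3.418,37.2
Mulata,P,0.995,1.106,3.6
Mulata,K,3.370,3.504,39.5
Mulata,Ca,2.560,2.725,17.9
Mulata,Mg,0.724,0.898,2.9
Mulata,S,0.823,1.023,3.2
Mulata,B,-3.815,-3.611,0.031
Mulata,Cu,-4.862,-4.406,0.012
Mulata,Zn,-3.681,-3.395,0.037
Mulata,Mn,-2.825,-2.655,0.082
Mulata,Fe,-4.362,-3.983,0.020
Mulata,Fv,6.522,6.592,895.5
Omega,N,3.109,3.177,25.6
Omega,P,1.073,1.137,3.3
Omega,K,3.265,3.341,30.1
Omega,Ca,2.624,2.726,16.1
Omega,Mg,0.917,1.017,2.9
Omega,S,0.912,1.013,2.9
Omega,B,-3.619,-3.536,0.031
Omega,Cu,-5.067,-4.832,0.008
Omega,Zn,-3.628,-3.464,0.032
Omega,Mn,-2.913,-2.813,0.063
Omega,Fe,-4.040,-3.842,0.021
Omega,Fv,6.701,6.743,918.9
SCS373 Valessul,N,3.172,3.262,26.8
SCS373 Valessul,P,1.864,1.913,7.1
SCS373 Valessul,K,3/234,3.314,28.4
SCS373 Valessul,Ca,2.011,2.117,8.5
SCS373 Valessul,Mg,0.864,0.919,2.6
SCS373 Valessul,S,1.369,1.475,4.4
SCS373 Valessul,B,-4.063,-3.973,0.019
SCS373 Valessul,Cu,-4.687,-4.398,0.011
SCS373 Valessul,Zn,-3.873,-3.784,0.023
SCS373 Valessul,Mn,-4.089,-3.954,0.019
SCS373 Valessul,Fe,-3.147,-3.058,0.048
SCS373 Valessul,Fv,6.722,6.789,922.1
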