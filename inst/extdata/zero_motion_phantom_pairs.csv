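method,acquisition,reference_acquisition,t_ml,t_dp,t_pa,r_fe,r_ei,r_vv
MMRI-M,1,2,-0.367,1.657,0.129,-1.460,0.984,0.557
MMRI-M,2,3,0.241,-1.313,-0.446,0.682,0.681,1.846
MMRI-M,3,4,-0.158,0.711,-0.535,0.829,-0.107,-0.960
MMRI-M,4,5,0.857,-0.209,0.359,-1.183,0.386,-0.952
MMRI-M,5,6,-0.258,-0.116,-0.424,1.623,-0.080,2.125
MMRI-M,6,7,0.912,0.426,-0.428,2.272,1.039,-0.748
MMRI-M,7,8,-0.724,-0.525,0.885,-3.657,-0.109,-1.624
MMRI-M,8,9,-0.146,1.334,-0.699,0.518,0.570,0.456
MMRI-M,9,10,-0.084,-1.207,-0.295,-1.197,-1.780,-0.821
MMRI-M,10,11,1.231,-0.372,0.985,0.775,0.712,0.291
MMRI-M,11,12,0.135,0.516,-0.118,0.465,0.781,0.301
MMRI-M,12,1,-0.105,-0.642,-0.833,0.939,-1.252,-0.398
MMRI-A,1,2,0.288,-0.561,1.836,1.506,0.936,-1.022
MMRI-A,2,3,1.571,-2.674,-2.178,2.964,0.900,6.187
MMRI-A,3,4,-0.738,3.648,0.381,-2.857,0.298,-3.799
MMRI-A,4,5,-0.040,-2.650,-0.001,0.952,-0.840,1.247
MMRI-A,5,6,-1.006,-1.651,-1.670,-4.091,-0.321,3.394
MMRI-A,6,7,1.210,0.226,1.094,1.968,1.573,-3.264
MMRI-A,7,8,1.489,0.986,0.597,2.472,1.206,-1.856
MMRI-A,8,9,-2.071,0.131,-0.667,-5.606,-1.682,0.943
MMRI-A,9,10,-0.568,2.232,-0.203,1.584,-4.138,2.737
MMRI-A,10,11,0.535,0.079,0.495,0.628,1.160,-0.290
MMRI-A,11,12,1.565,-1.566,-1.880,2.888,0.125,3.453
MMRI-A,12,1,-0.470,1.964,1.167,-2.522,0.393,-7.439
MMRI-W,1,2,-0.326,-0.173,1.702,1.725,-0.779,-0.735
MMRI-W,2,3,1.315,-0.736,-1.071,-0.359,1.727,0.665
MMRI-W,3,4,0.094,0.356,-0.081,2.417,0.516,-0.291
MMRI-W,4,5,0.467,-0.804,0.716,-0.789,-0.416,0.502
MMRI-W,5,6,-0.432,2.489,-1.456,-2.723,-0.360,-0.305
MMRI-W,6,7,1.229,-3.267,0.182,4.319,0.750,0.416
MMRI-W,7,8,0.196,0.690,-0.240,-2.665,0.295,0.291
MMRI-W,8,9,0.369,1.619,-0.062,2.500,0.206,-0.068
MMRI-W,9,10,-2.113,1.378,0.618,-3.284,-2.317,-1.114
MMRI-W,10,11,0.577,-1.102,-0.718,0.452,0.553,0.383
MMRI-W,11,12,1.669,0.119,-1.792,1.847,1.364,2.007
MMRI-W,12,1,-1.414,-0.956,0.746,-2.623,-1.781,-1.790
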