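"time_s","Fo","Fm","Fp","TFA"
0,2.05559706741518,1.94521005085531,1.03863138363974,0.984433253886663
272.727272727273,1.45345593811499,1.46179088022421,0.728681550106796,0.98312583888722
545.454545454545,1.0882724894826,1.07752050396211,0.53742634040754,0.952862989729284
818.181818181818,0.804187490324677,0.804237155150028,0.383279598313611,1.00072271316925
1090.90909090909,0.588367329197569,0.580320790363187,0.294512327836814,1.00412847075619
1363.63636363636,0.428047647223778,0.406761857130309,0.211750760900708,0.992804863859011
1636.36363636364,0.32495228430773,0.300256940225629,0.159080400190571,1.01527881028972
1909.09090909091,0.231283826490354,0.23792157203333,0.117505881701222,0.985571013596479
2181.81818181818,0.177327482471399,0.169270319444408,0.0869370785684601,0.973005425373363
2454.54545454545,0.125019079215532,0.120794949116934,0.0618303864215,1.00869393514807
2727.27272727273,0.0944347333525615,0.0916863215878158,0.0464679799586328,0.983903098883218
3000,0.0707841685323949,0.0692827497272864,0.0326686239616436,1.02930315551343
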