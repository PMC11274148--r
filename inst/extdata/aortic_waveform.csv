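"t_s","q_m3s"
0,0
0.0125,3.8433787474466e-05
0.025,7.6154106133524e-05
0.0375,0.000112460731699554
0.05,0.000146679683104434
0.0625,0.000178175733993239
0.075,0.000206364204801598
0.0875,0.000230721816503495
0.1,0.000250796404545054
0.1125,0.000266215312638904
0.125,0.000276692310600215
0.1375,0.000282032907804572
0.15,0.000282137963630888
0.1625,0.000277005527866579
0.175,0.000266730876910501
0.1875,0.000251504745101579
0.2,0.000231609784006022
0.2125,0.000207415315391424
0.225,0.000179370475291369
0.2375,0.000147995876431256
0.25,0.000113873943790603
0.2625,7.7638102708424e-05
0.275,3.99610202391786e-05
0.2875,1.54211804187514e-06
0.3,-1.02690231752255e-05
0.3125,-1.85570434654144e-05
0.325,-2.24626792959457e-05
0.3375,-2.10635855852498e-05
0.35,-1.46901687661608e-05
0.3625,-4.84755883823669e-06
0.375,5.65486677646163e-06
0.3875,5.65486677646163e-06
0.4,5.65486677646163e-06
0.4125,5.65486677646163e-06
0.425,5.65486677646163e-06
0.4375,5.65486677646163e-06
0.45,5.65486677646163e-06
0.4625,5.65486677646163e-06
0.475,5.65486677646163e-06
0.4875,5.65486677646163e-06
0.5,5.65486677646163e-06
0.5125,5.65486677646163e-06
0.525,5.65486677646163e-06
0.5375,5.65486677646163e-06
0.55,5.65486677646163e-06
0.5625,5.65486677646163e-06
0.575,5.65486677646163e-06
0.5875,5.65486677646163e-06
0.6,5.65486677646163e-06
0.6125,5.65486677646163e-06
0.625,5.65486677646163e-06
0.6375,5.65486677646163e-06
0.65,5.65486677646163e-06
0.6625,5.65486677646163e-06
0.675,5.65486677646163e-06
0.6875,5.65486677646163e-06
0.7,5.65486677646163e-06
0.7125,5.65486677646163e-06
0.725,5.65486677646163e-06
0.7375,5.65486677646163e-06
0.75,5.65486677646163e-06
0.7625,5.65486677646163e-06
0.775,5.65486677646163e-06
0.7875,5.65486677646163e-06
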