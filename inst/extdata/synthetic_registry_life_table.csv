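sex,age,m,q
female,40,0.0015979470333103392,0.0015966709957203618
female,41,0.0017013454087186014,0.0016998989410487164
female,42,0.0018144812520672188,0.0018128360761575646
female,43,0.001938271582424577,0.0019363943471207845
female,44,0.0020737197784729718,0.0020715711071171983
female,45,0.0022219237113633855,0.0022194570661112634
female,46,0.0023840846434760496,0.002381244970804053
female,47,0.0025615169652153926,0.0025582390800173993
female,48,0.0027556588487606935,0.002751865506101403
female,49,0.0029680839051260503,0.0029636834987605276
female,50,0.0032005139390156546,0.0031953977538747846
female,51,0.0034548329048583893,0.0034488718364658055
female,52,0.003733102177142014,0.003726142813907596
female,53,0.004037577258820119,0.004029437202813124
female,54,0.004370726063221344,0.0043611883407119745
female,55,0.004735248917644305,0.004724055301643992
female,56,0.005134100450776726,0.0051209434830854494
female,57,0.005570513541346616,0.005555027000129109
female,58,0.006048025522120502,0.006029773031477226
female,59,0.006570506851644425,0.006548968270450373
female,60,0.007142192486125609,0.0071167476427316245
female,61,0.007767716205738625,0.007737625460741859
female,62,0.008452148173586808,0.008416529192158517
female,63,0.009201036031752041,0.009158836026823547
female,64,0.010020449867535515,0.009970412431769105
female,65,0.010917031414362035,0.01085765688785667
female,66,0.011898047886144252,0.011827546003003508
female,67,0.012971450881459571,0.012887684195465932
female,68,0.014145940834985752,0.01404635713532465
female,69,0.015431037538604213,0.015312589122152165
female,70,0.01683715730377787,0.016696204560626926
female,71,0.018375697390640492,0.018207893672132158
female,72,0.02005912838813516,0.019859282547414536
female,73,0.02190109529398603,0.02166300760113149
female,74,0.02391652811380413,0.023632794431173942
female,75,0.02612176287578455,0.02578354101118996
female,76,0.028534674041876304,0.0281314050504633
female,77,0.031174819388679057,0.03069389523739341
female,78,0.0340635985323946,0.0334899659369029
female,79,0.037224426382752106,0.036540114733127904
female,80,0.04068292293183251,0.0398664819910487
female,81,0.04446712091611954,0.0434929513478971
female,82,0.04860769303497546,0.04744524973016506
female,83,0.0531382005672544,0.051751045117073735
female,84,0.05809536540120678,0.056440039828133504
female,85,0.06351936768260527,0.06154405659219886
female,86,0.0694541714936699,0.06709711404928043
female,87,0.07594788120257255,0.07313548763568634
female,88,0.08305313137190061,0.07969775099993115
female,89,0.09082751338647148,0.08682479218502526
female,90,0.0993340422585152,0.09455979778859813
female,91,0.10864166739390135,0.10294819717631276
female,92,0.1188258314594091,0.11203755758260125
female,93,0.12996908188092238,0.12187741960064069
female,94,0.14216173992902945,0.13251906116674494
female,95,0.15550263281527957,0.14401517672395936
female,96,0.17009989473308054,0.15641945686597203
female,97,0.18607184333604745,0.1697860525003002
female,98,0.2035479387580752,0.18416890654420148
female,99,0.22266983294843634,0.1996209355295694
female,100,0.24359251782726155,0.21619304343896084
female,101,0.26648558156773994,0.23393295086758026
female,102,0.2915345831877956,0.25288382450281144
female,103,0.3189425565929507,0.2730826952863338
female,104,0.34893165626134764,0.2945586588788671
female,105,0.3817449579099801,0.31733085963097873
male,40,0.002429911722183899,0.002426961876467071
male,41,0.0026022423478643357,0.0025988594502551754
male,42,0.002790802086778698,0.002786911418837912
male,43,0.0029971193040409616,0.0029926324256689396
male,44,0.0032228662974549526,0.003217678438624305
male,45,0.0034698728522723093,0.003463859800319269
male,46,0.0037401410724600824,0.0037331554566157887
male,47,0.004035861608692321,0.004027728464323976
male,48,0.004359431414601156,0.004349942886675007
male,49,0.004713473175210084,0.0047023821930481935
male,50,0.005100856565026091,0.005087869287640601
male,51,0.005524721508097316,0.005509488300214027
male,52,0.005988503628570023,0.005970608280653655
male,53,0.006495962098033531,0.006474908947732949
male,54,0.007051210105368907,0.007026408651052751
male,55,0.007658748196073843,0.007629494713433882
male,56,0.008323500751294543,0.008288956328867392
male,57,0.009050855902244359,0.009010020198185975
male,58,0.009846709203534169,0.009798389090551973
male,59,0.010717511419407374,0.01066028352323789
male,60,0.011670320810209349,0.011602486754465735
male,61,0.012712860342897708,0.012632393283616428
male,62,0.013853580289311345,0.013758061049140125
male,63,0.015101726719586733,0.014988267506022224
male,64,0.016467416445892523,0.016332569750558634
male,65,0.017961719023936725,0.01780136883907446
male,66,0.019596746476907085,0.019405978417467606
male,67,0.021385751469099285,0.02115869773811485
male,68,0.02334323472497625,0.02307288908747207
male,69,0.025485062564340355,0.025163059578938385
male,70,0.02782859550629645,0.027444947178099977
male,71,0.03039282898440082,0.02993561071769313
male,72,0.0331985473135586,0.03265352352331474
male,73,0.036268492156643385,0.03561867010325781
male,74,0.039627546856340214,0.03885264515139386
male,75,0.04330293812630758,0.04237875386459655
male,76,0.04732445673646051,0.0462221122789529
male,77,0.051724698981131766,0.05040974597439962
male,78,0.05653933088732434,0.05497068507730796
male,79,0.061807377304586845,0.059936052996291456
male,80,0.06757153821972085,0.06533914574925015
male,81,0.07387853486019923,0.07121549807060501
male,82,0.08077948839162577,0.07760293171860633
male,83,0.08833033427875735,0.08454158052665184
male,84,0.09659227566867797,0.09207388575507536
male,85,0.1056322794710088,0.10024455419986811
male,86,0.11552361915611652,0.10910047030650039
male,87,0.12634646867095425,0.11869055223219205
male,88,0.138188552286501,0.12906554042063656
male,89,0.15114585564411911,0.14027770583502785
male,90,0.16532340376419202,0.15238046359180146
male,91,0.1808361123231689,0.16542787642507506
male,92,0.19780971909901515,0.17947403129493877
male,93,0.21638180313487065,0.19457227167064362
male,94,0.23670289988171575,0.21077426775241526
male,95,0.2589377213587993,0.2281289073703352
male,96,0.28326649122180086,0.24668099179500458
male,97,0.30988640556007907,0.26646972354723897
male,98,0.33901323126345867,0.2875269778914362
male,99,0.37088305491406054,0.3098753564744061
male,100,0.4057541963787692,0.3335260309924114
male,101,0.44390930261289985,0.3584763972966638
male,102,0.485657638646326,0.38470757639491715
male,103,0.5313375943215844,0.4121818186676236
male,104,0.581319427102246,0.44083989136808266
male,105,0.6360082631833002,0.4705985568505434
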