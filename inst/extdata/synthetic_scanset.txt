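# sedgrid scanset v1
meniscus: 5.9000000000000004
bottom: 7.2000000000000002
omega: 3141.5926535897934
temperature: 293.14999999999998
wavelength: 300
d2o_fraction: 0.14999999999999999
density_increment: 0.0045999999999999999
viscosity_multiplier: 1
scan 1 time 3600
5.9500000000000002,0.00056241065088404323
5.9913793103448274,0.022311578476910569
6.0327586206896555,0.17206271616370561
6.0741379310344827,0.49812295259576206
6.1155172413793109,0.78580639760238946
6.1568965517241381,0.90976867098504421
6.1982758620689662,0.93923985171391267
6.2396551724137934,0.94338465492297785
6.2810344827586206,0.94374603067336382
6.3224137931034488,0.94376807804631346
6.363793103448276,0.9437690520126808
6.4051724137931041,0.94376908218891786
6.4465517241379313,0.94376908286001127
6.4879310344827585,0.94376908287094929
6.5293103448275867,0.94376908287111472
6.5706896551724139,0.94376908287110273
6.612068965517242,0.94376908287111261
6.6534482758620692,0.94376908287110528
6.6948275862068964,0.94376908287110173
6.7362068965517246,0.94376908287110506
6.7775862068965518,0.94376908287112149
6.8189655172413799,0.94376908287112016
6.8603448275862071,0.94376908287111161
6.9017241379310352,0.94376908287110384
6.9431034482758625,0.94376908287111738
6.9844827586206897,0.94376908287111416
7.0258620689655178,0.94376908287110428
7.067241379310345,0.94376908287108952
7.1086206896551722,0.94376908287110128
7.1500000000000004,0.94376908287115879
scan 2 time 10800
5.9500000000000002,1.3954222348244281e-15
5.9913793103448274,2.3141253400100457e-12
6.0327586206896555,6.2496721757264954e-10
6.0741379310344827,5.5733949534075093e-08
6.1155172413793109,2.4210293662423914e-06
6.1568965517241381,5.0051478326109704e-05
6.1982758620689662,0.00057229550064397453
6.2396551724137934,0.0040348830027648729
6.2810344827586206,0.019270227410728376
6.3224137931034488,0.064863137888971426
6.363793103448276,0.1606101166799265
6.4051724137931041,0.30797198307186791
6.4465517241379313,0.47911602066457826
6.4879310344827585,0.63177186393013895
6.5293103448275867,0.73870446048279481
6.5706896551724139,0.79877176218486157
6.612068965517242,0.82616860384134316
6.6534482758620692,0.83640167719836889
6.6948275862068964,0.83955183339233797
6.7362068965517246,0.84038674091015197
6.7775862068965518,0.84057411483311895
6.8189655172413799,0.84060988721135066
6.8603448275862071,0.84061570190348356
6.9017241379310352,0.84061653420810123
6.9431034482758625,0.84061664128975044
6.9844827586206897,0.84061665326199053
7.0258620689655178,0.8406166544298731
7.067241379310345,0.84061665452916412
7.1086206896551722,0.84061665453714918
7.1500000000000004,0.84061665453785417
scan 3 time 21600
5.9500000000000002,2.6938958971377024e-34
5.9913793103448274,3.8085215906249639e-30
6.0327586206896555,9.1860130888486673e-27
6.0741379310344827,6.9694199283488044e-24
6.1155172413793109,3.3808274082977073e-21
6.1568965517241381,7.5398885965841024e-19
6.1982758620689662,8.7847821678939578e-17
6.2396551724137934,5.8598268153220321e-15
6.2810344827586206,2.7445479373283267e-13
6.3224137931034488,9.2992105385745462e-12
6.363793103448276,2.1642891128028216e-10
6.4051724137931041,3.6071304833937668e-09
6.4465517241379313,4.464300690486798e-08
6.4879310344827585,4.5221031309008833e-07
6.5293103448275867,3.5964810623627786e-06
6.5706896551724139,2.2721691590856704e-05
6.612068965517242,0.00011648629863234916
6.6534482758620692,0.00049572430466520085
6.6948275862068964,0.0018026474126071885
6.7362068965517246,0.0055405561740421039
6.7775862068965518,0.014601740948747575
6.8189655172413799,0.033431315121217754
6.8603448275862071,0.06742442945109986
6.9017241379310352,0.12087462787020746
6.9431034482758625,0.19422253228052594
6.9844827586206897,0.28302818055538354
7.0258620689655178,0.37846204982393261
7.067241379310345,0.46979170516612179
7.1086206896551722,0.54798994178047356
7.1500000000000004,0.60829696480374673
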