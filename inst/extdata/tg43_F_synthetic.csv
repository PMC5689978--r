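theta_deg,r0.25,r0.5,r1,r2,r3,r4,r5,r8,r12
0,0.8475,0.845,0.84,0.83,0.82,0.81,0.8,0.77,0.73
1,0.84756966885397,0.84507081096633,0.84007309519105,0.830077663640491,0.820082232089931,0.810086800539372,0.800091368988813,0.770105074337134,0.730123348134897
2,0.847778526898775,0.84528309291351,0.840292224942978,0.830310489001914,0.82032875306085,0.810347017119786,0.800365281178722,0.77042007335553,0.730493129591275
5,0.849234309278486,0.846762740578133,0.841819603177428,0.831933328376017,0.822047053574606,0.812160778773195,0.802274503971785,0.772615679567553,0.733070580361909
10,0.854345394729947,0.851957614315684,0.847182053487157,0.837630931830105,0.828079810173052,0.818528688515999,0.808977566858947,0.780324201887789,0.742119715259578
20,0.873460156497612,0.871385732833638,0.867236885505691,0.858939190849797,0.850641496193902,0.842343801538008,0.834046106882114,0.809153022914431,0.775962244290853
30,0.900948344442155,0.899324546810059,0.896076951545867,0.889581761017484,0.883086570489101,0.876591379960717,0.870096189432334,0.850610617847184,0.824629855733651
40,0.931446166818267,0.930322333487419,0.928074666825723,0.92357933350233,0.919084000178938,0.914588666855546,0.910093333532153,0.896607333561976,0.878626000268407
50,0.959498385661384,0.958834424770587,0.957506502988993,0.954850659425805,0.952194815862617,0.949538972299429,0.946883128736241,0.938915598046677,0.928292223793925
60,0.9809375,0.980625,0.98,0.97875,0.9775,0.97625,0.975,0.97125,0.96625
70,0.993898664626408,0.993798642735038,0.993598598952297,0.993198511386816,0.992798423821334,0.992398336255853,0.991998248690372,0.990797985993927,0.989197635732002
80,0.999201489679345,0.999188399346219,0.999162218679968,0.999109857347466,0.999057496014964,0.999005134682462,0.99895277334996,0.998795689352455,0.998586244022447
90,1,1,1,1,1,1,1,1,1
100,0.999201489679345,0.999188399346219,0.999162218679968,0.999109857347466,0.999057496014964,0.999005134682462,0.99895277334996,0.998795689352455,0.998586244022447
110,0.993898664626408,0.993798642735038,0.993598598952297,0.993198511386816,0.992798423821334,0.992398336255853,0.991998248690372,0.990797985993927,0.989197635732002
120,0.9809375,0.980625,0.98,0.97875,0.9775,0.97625,0.975,0.97125,0.96625
130,0.959498385661384,0.958834424770587,0.957506502988993,0.954850659425805,0.952194815862617,0.949538972299429,0.946883128736241,0.938915598046677,0.928292223793925
140,0.931446166818267,0.930322333487419,0.928074666825723,0.92357933350233,0.919084000178938,0.914588666855546,0.910093333532153,0.896607333561976,0.878626000268407
150,0.900948344442155,0.899324546810059,0.896076951545867,0.889581761017484,0.883086570489101,0.876591379960717,0.870096189432334,0.850610617847184,0.824629855733651
160,0.873460156497612,0.871385732833638,0.867236885505691,0.858939190849797,0.850641496193902,0.842343801538008,0.834046106882114,0.809153022914431,0.775962244290854
170,0.854345394729947,0.851957614315684,0.847182053487157,0.837630931830105,0.828079810173052,0.818528688515999,0.808977566858947,0.780324201887789,0.742119715259578
175,0.849234309278486,0.846762740578133,0.841819603177428,0.831933328376017,0.822047053574606,0.812160778773195,0.802274503971785,0.772615679567553,0.733070580361909
178,0.847778526898775,0.84528309291351,0.840292224942978,0.830310489001914,0.82032875306085,0.810347017119786,0.800365281178722,0.77042007335553,0.730493129591275
179,0.84756966885397,0.84507081096633,0.84007309519105,0.830077663640491,0.820082232089931,0.810086800539372,0.800091368988813,0.770105074337134,0.730123348134897
180,0.8475,0.845,0.84,0.83,0.82,0.81,0.8,0.77,0.73
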