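"gene","culture","passage","lysate","tech_rep","cq"
"GOI1","A1",28,1,1,24.0735261140997
"GOI1","A1",28,1,2,24.4120774901429
"GOI1","A1",28,1,3,23.8961483758067
"GOI1","A1",28,2,1,24.0707844858353
"GOI1","A1",28,2,2,24.2152701914047
"GOI1","A1",28,2,3,23.8597702814875
"GOI1","A1",28,3,1,23.9225288593549
"GOI1","A1",28,3,2,24.0906318683478
"GOI1","A1",28,3,3,24.0295215989278
"GOI1","A1",29,1,1,23.5113867961144
"GOI1","A1",29,1,2,23.6567363710966
"GOI1","A1",29,1,3,23.7343306668202
"GOI1","A1",29,2,1,23.7955803010241
"GOI1","A1",29,2,2,23.9215017588339
"GOI1","A1",29,2,3,23.9267784153764
"GOI1","A1",29,3,1,23.6446274098619
"GOI1","A1",29,3,2,23.4070081732181
"GOI1","A1",29,3,3,23.6380556384546
"GOI1","A1",30,1,1,23.9668556498585
"GOI1","A1",30,1,2,24.4045542665726
"GOI1","A1",30,1,3,24.103868869878
"GOI1","A1",30,2,1,24.2233845564771
"GOI1","A1",30,2,2,24.3675116384707
"GOI1","A1",30,2,3,24.3862422838994
"GOI1","A1",30,3,1,23.8986931066908
"GOI1","A1",30,3,2,23.7330307658307
"GOI1","A1",30,3,3,23.8529897168792
"GOI1","A1",31,1,1,23.8628068976018
"GOI1","A1",31,1,2,24.0359063075162
"GOI1","A1",31,1,3,24.1268156745161
"GOI1","A1",31,2,1,24.0677191090293
"GOI1","A1",31,2,2,24.3296433382812
"GOI1","A1",31,2,3,23.9422110892369
"GOI1","A1",31,3,1,23.952110085853
"GOI1","A1",31,3,2,23.6712981968967
"GOI1","A1",31,3,3,23.8516622446892
"GOI1","A1",32,1,1,24.0950847267104
"GOI1","A1",32,1,2,24.3481388083126
"GOI1","A1",32,1,3,24.1404456580145
"GOI1","A1",32,2,1,24.2299473295645
"GOI1","A1",32,2,2,24.0093835792851
"GOI1","A1",32,2,3,24.3510452776752
"GOI1","A1",32,3,1,23.6914098719749
"GOI1","A1",32,3,2,24.3763724786628
"GOI1","A1",32,3,3,24.1440875250542
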