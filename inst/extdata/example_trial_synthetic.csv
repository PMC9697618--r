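subject,sequence,period,treatment,log_value
1,TRR,1,T,0.37194420352780744
1,TRR,2,R,0.13970922795269164
1,TRR,3,R,-0.1202965524548207
2,TRR,1,T,-0.35792768528835184
2,TRR,2,R,-0.3237682972889606
2,TRR,3,R,-0.45736046154482
3,TRR,1,T,0.3613919112965545
3,TRR,2,R,0.2823385031500308
3,TRR,3,R,0.37585336399454244
4,TRR,1,T,0.35858734154263017
4,TRR,2,R,0.21318387768781416
4,TRR,3,R,0.15778733935264289
5,TRR,1,T,-0.31448373411270214
5,TRR,2,R,-0.2581792657991506
5,TRR,3,R,-0.22396522938484348
6,TRR,1,T,-0.10538002431988397
6,TRR,2,R,-0.18335236278286826
6,TRR,3,R,-0.30708178019094046
7,TRR,1,T,0.8207921506630763
7,TRR,2,R,0.6281680790172216
7,TRR,3,R,0.48152588474983715
8,TRR,1,T,-0.31776234074248655
8,TRR,2,R,-0.057338158531624106
8,TRR,3,R,-0.29668996342135223
9,RTR,1,R,-0.23120846140808843
9,RTR,2,T,0.2505072787696793
9,RTR,3,R,0.05183240475069318
10,RTR,1,R,-0.1282655484158673
10,RTR,2,T,-0.42973697170327757
10,RTR,3,R,-0.4742725524312566
11,RTR,1,R,0.3230932022500786
11,RTR,2,T,-0.12423695578478866
11,RTR,3,R,0.1413489520869389
12,RTR,1,R,0.3282273545360282
12,RTR,2,T,0.6402280221768109
12,RTR,3,R,0.48385786308191986
13,RTR,1,R,-0.18974866145855035
13,RTR,2,T,0.1326992916506562
13,RTR,3,R,0.2273615016194637
14,RTR,1,R,0.3505802115247263
14,RTR,2,T,0.22337228557594901
14,RTR,3,R,2.4586534455278697e-5
15,RTR,1,R,0.23703590617431833
15,RTR,2,T,0.3329225256122147
15,RTR,3,R,0.38460530360311745
16,RTR,1,R,-0.01603461659298181
16,RTR,2,T,-0.12073083571240595
16,RTR,3,R,0.024574835364718363
17,RRT,1,R,0.12506886182914592
17,RRT,2,R,-0.025754105496071683
17,RRT,3,T,-0.3124562448364129
18,RRT,1,R,-0.06993288269975567
18,RRT,2,R,0.1266696410966565
18,RRT,3,T,0.04321864811361609
19,RRT,1,R,0.0790174809582163
19,RRT,2,R,0.24335370189303085
19,RRT,3,T,-0.03357321160171346
20,RRT,1,R,-0.5982786411723512
20,RRT,2,R,-0.4513257742433564
20,RRT,3,T,-0.20785495398331327
21,RRT,1,R,-0.16896946649067188
21,RRT,2,R,0.18750037149923743
21,RRT,3,T,0.12293083191667928
22,RRT,1,R,-0.8631146204676595
22,RRT,2,R,-0.613481373607206
22,RRT,3,T,-0.7353477493074708
23,RRT,1,R,0.0066937256438838345
23,RRT,2,R,-0.011873448946457851
23,RRT,3,T,-0.31726302363969167
24,RRT,1,R,0.06796203262944372
24,RRT,2,R,0.2552694364623351
24,RRT,3,T,0.0964934732671894
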