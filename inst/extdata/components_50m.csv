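date,character,component,density,mean,sd,generation
2014-05-09,NoC,1,7,50.7,9.59,1
2014-05-09,NoC,2,14,36.0,5.46,2
2014-05-30,NoC,1,4,56.3,5.80,1
2014-05-30,NoC,2,3,38.6,2.87,2
2014-08-19,NoC,1,6,51.8,3.82,1
2014-08-19,NoC,2,3,29.2,7.26,3
2014-09-10,NoC,1,3,59.1,4.81,1
2014-09-10,NoC,2,5,38.2,5.14,3
2014-11-10,NoC,1,2,49.9,3.68,2
2014-11-10,NoC,2,6,33.6,3.04,3
2014-12-11,NoC,1,5,64.7,6.84,1
2014-12-11,NoC,2,3,51.8,7.80,2
2014-12-11,NoC,3,3,30.4,3.28,3
2015-01-16,NoC,1,5,52.6,4.10,2
2015-01-16,NoC,2,7,33.1,7.13,3
2015-02-13,NoC,1,3,55.1,3.29,2
2015-02-13,NoC,2,3,38.0,6.06,3
2015-04-15,NoC,1,11,56.5,1.95,2
2015-04-15,NoC,2,7,42.5,8.92,3
2015-05-18,NoC,1,11,56.5,3.95,2
2015-05-18,NoC,2,3,40.0,7.03,3
2015-06-11,NoC,1,3,56.4,4.57,2
2015-06-11,NoC,2,6,42.5,2.36,3
2015-06-11,NoC,3,8,28.4,6.49,4
2015-07-14,NoC,1,3,61.9,2.70,2
2015-07-14,NoC,2,9,46.0,7.66,3
2015-07-14,NoC,3,4,29.6,4.19,4
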