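date,character,component,density,mean,sd,generation
2014-05-02,NoC,1,8,54.6,9.79,1
2014-05-02,NoC,2,2,33.2,2.54,2
2014-05-30,NoC,1,7,56.3,7.85,1
2014-05-30,NoC,2,1,39.5,3.25,2
2014-07-18,NoC,1,7,52.4,4.53,1
2014-07-18,NoC,2,4,37.3,4.64,2
2014-08-19,NoC,1,4,52.0,8.91,1
2014-08-19,NoC,2,11,40.8,7.38,2
2014-09-10,NoC,1,7,50.8,5.35,2
2014-09-10,NoC,2,11,36.6,6.07,3
2014-10-20,NoC,1,11,50.8,3.32,2
2014-10-20,NoC,2,13,31.0,3.86,3
2014-12-11,NoC,1,11,45.4,3.35,2
2014-12-11,NoC,2,8,30.6,3.82,3
2015-02-13,NoC,1,1,54.1,6.02,2
2015-02-13,NoC,2,5,46.5,5.79,3
2015-03-03,NoC,1,13,53.4,6.17,2
2015-03-03,NoC,2,7,40.9,5.09,3
2015-06-11,NoC,1,11,48.5,6.05,3
2015-06-11,NoC,2,7,29.1,6.46,4
2015-07-14,NoC,1,11,48.0,5.98,3
2015-07-14,NoC,2,8,30.3,6.46,4
2014-05-02,TD,1,16,2697.8,519.57,1
2014-05-02,TD,2,9,1049.7,43.14,2
2014-05-30,TD,1,5,2801.8,782.35,1
2014-05-30,TD,2,6,1683.8,52.77,2
2014-07-18,TD,1,8,2567.0,306.56,1
2014-07-18,TD,2,10,1466.9,91.93,2
2014-08-19,TD,1,4,3354.0,374.11,1
2014-08-19,TD,2,13,1772.3,403.07,2
2014-09-10,TD,1,8,2456.5,429.63,2
2014-09-10,TD,2,6,1330.9,322.40,3
2014-10-20,TD,1,8,2043.2,693.81,2
2014-10-20,TD,2,3,997.2,54.20,3
2014-12-11,TD,1,8,2203.2,612.81,2
2014-12-11,TD,2,5,1312.4,67.16,3
2015-02-13,TD,1,4,2385.7,487.16,2
2015-02-13,TD,2,2,1504.2,282.67,3
2015-03-03,TD,1,18,2669.2,503.46,2
2015-03-03,TD,2,8,1479.8,91.28,3
2015-06-11,TD,1,9,1919.5,638.80,3
2015-06-11,TD,2,8,1009.7,71.64,4
2015-07-14,TD,1,10,1976.7,424.92,3
2015-07-14,TD,2,8,1010.9,210.80,4
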