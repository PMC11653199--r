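&FCI NORB=3,NELEC=4,MS2=0,
 ORBSYM=1,2,3,
 ISYM=1,
&END
6.7210000000000003e-01    1    1    1    1
1.4119999999999999e-01    2    1    2    1
5.5830000000000002e-01    2    2    1    1
5.8940000000000003e-01    2    2    2    2
1.0979999999999999e-01    3    1    3    1
1.7630000000000001e-01    3    2    3    2
5.2390000000000003e-01    3    3    1    1
4.8740000000000000e-01    3    3    2    2
5.4769999999999996e-01    3    3    3    3
-6.8411999999999997e+00    1    1    0    0
-5.9236000000000004e+00    2    2    0    0
-5.1184000000000003e+00    3    3    0    0
-3.7442100000000003e+01    0    0    0    0
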