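0.0000000000000000e+00	0.0000000000000000e+00	3.3275146395041411e-01	5.6009173582869609e-01	0.0000000000000000e+00	0.0000000000000000e+00	0.0000000000000000e+00	0.0000000000000000e+00
0.0000000000000000e+00	0.0000000000000000e+00	3.1771699735006909e-01	0.0000000000000000e+00	0.0000000000000000e+00	0.0000000000000000e+00	0.0000000000000000e+00	0.0000000000000000e+00
3.3275146395041411e-01	3.1771699735006909e-01	0.0000000000000000e+00	0.0000000000000000e+00	0.0000000000000000e+00	0.0000000000000000e+00	0.0000000000000000e+00	0.0000000000000000e+00
5.6009173582869609e-01	0.0000000000000000e+00	0.0000000000000000e+00	0.0000000000000000e+00	0.0000000000000000e+00	0.0000000000000000e+00	0.0000000000000000e+00	1.9215717689648045e-03
0.0000000000000000e+00	0.0000000000000000e+00	0.0000000000000000e+00	0.0000000000000000e+00	0.0000000000000000e+00	2.4897168282235017e-02	9.3488516317421898e-03	1.0000000000000000e+00
0.0000000000000000e+00	0.0000000000000000e+00	0.0000000000000000e+00	0.0000000000000000e+00	2.4897168282235017e-02	0.0000000000000000e+00	2.4654221427305639e-01	2.6907801763125832e-02
0.0000000000000000e+00	0.0000000000000000e+00	0.0000000000000000e+00	0.0000000000000000e+00	9.3488516317421898e-03	2.4654221427305639e-01	0.0000000000000000e+00	0.0000000000000000e+00
0.0000000000000000e+00	0.0000000000000000e+00	0.0000000000000000e+00	1.9215717689648045e-03	1.0000000000000000e+00	2.6907801763125832e-02	0.0000000000000000e+00	0.0000000000000000e+00
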