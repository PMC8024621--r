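0.0000000000000000e+00	1.4219589070603471e+01	2.5085056630744120e+01	2.6200887018299291e+01	6.7046770349069803e+01	2.4512306318291103e+01	6.0997166601657426e+01	7.7251255928295677e+01
1.4219589070603471e+01	0.0000000000000000e+00	1.2860909627861840e+01	3.2484011756331562e+01	5.2843927932852928e+01	1.2596019697343031e+01	5.0047080830618974e+01	6.4778871346522337e+01
2.5085056630744120e+01	1.2860909627861840e+01	0.0000000000000000e+00	3.4988592058901901e+01	4.4933735642142736e+01	1.4269291674253402e+01	4.4618680997660746e+01	5.7520503437940263e+01
2.6200887018299291e+01	3.2484011756331562e+01	3.4988592058901901e+01	0.0000000000000000e+00	7.8159715315661970e+01	4.3746941574029151e+01	6.2091654338840151e+01	9.1794837553412989e+01
6.7046770349069803e+01	5.2843927932852928e+01	4.4933735642142736e+01	7.8159715315661970e+01	0.0000000000000000e+00	4.4856856589199154e+01	4.1223921157974679e+01	3.1929529405927966e+01
2.4512306318291103e+01	1.2596019697343031e+01	1.4269291674253402e+01	4.3746941574029151e+01	4.4856856589199154e+01	0.0000000000000000e+00	5.2048633783637548e+01	5.3029351040136092e+01
6.0997166601657426e+01	5.0047080830618974e+01	4.4618680997660746e+01	6.2091654338840151e+01	4.1223921157974679e+01	5.2048633783637548e+01	0.0000000000000000e+00	7.1691462680079283e+01
7.7251255928295677e+01	6.4778871346522337e+01	5.7520503437940263e+01	9.1794837553412989e+01	3.1929529405927966e+01	5.3029351040136092e+01	7.1691462680079283e+01	0.0000000000000000e+00
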