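# synthetic orientation fixture: fibrin
center,value
2.5000000000000000e+00,1.4030244656388019e-03
7.4999999999999991e+00,1.1840597762454328e-02
1.2500000000000000e+01,3.1358312023732418e-02
1.7500000000000000e+01,5.9550274565931524e-02
2.2500000000000000e+01,9.9529951938951408e-02
2.7500000000000000e+01,1.4440167786329866e-01
3.2499999999999993e+01,1.8997200341729881e-01
3.7499999999999993e+01,2.3788148599443543e-01
4.2500000000000000e+01,2.8230595920817658e-01
4.7500000000000000e+01,3.3608259304107474e-01
5.2499999999999993e+01,3.8165485838319468e-01
5.7499999999999993e+01,4.5880279677430397e-01
6.2499999999999993e+01,5.1201483233548439e-01
6.7500000000000000e+01,5.4566135175477903e-01
7.2500000000000000e+01,5.2179688446296868e-01
7.7500000000000000e+01,5.9999750139228047e-01
8.2499999999999986e+01,6.0404564625197699e-01
8.7499999999999986e+01,6.3915577048582684e-01
9.2500000000000000e+01,6.0084593215333815e-01
9.7500000000000000e+01,5.8476133553284015e-01
1.0250000000000000e+02,6.2363677803928075e-01
1.0750000000000000e+02,5.8113208114195114e-01
1.1250000000000000e+02,5.5807227734485298e-01
1.1750000000000000e+02,4.9620960189750868e-01
1.2249999999999999e+02,4.5781535812926394e-01
1.2749999999999999e+02,3.8312636282348961e-01
1.3250000000000000e+02,3.4635057699371302e-01
1.3750000000000000e+02,2.9895069002919722e-01
1.4250000000000000e+02,2.2450813973224840e-01
1.4750000000000000e+02,1.8633657403807538e-01
1.5250000000000000e+02,1.3303794539131308e-01
1.5750000000000000e+02,9.5197684644917291e-02
1.6250000000000000e+02,5.9030179194655349e-02
1.6750000000000000e+02,3.2617402970944870e-02
1.7249999999999997e+02,1.1501797145931351e-02
1.7750000000000000e+02,1.3783112544851997e-03
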