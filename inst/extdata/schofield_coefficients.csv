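bracket,sex,gamma_kcal_per_kg,delta_kcal
0-3,male,59.512428298279154,-30.353728489483746
3-10,male,22.705544933078393,504.302103250478
10-18,male,17.68642447418738,658.2217973231358
18-30,male,15.05736137667304,692.1606118546845
30-60,male,11.47227533460803,873.0879541108986
60+,male,11.711281070745697,587.7151051625239
0-3,female,58.31739961759082,-31.070745697896747
3-10,female,20.31548757170172,485.8986615678776
10-18,female,13.38432122370937,692.6386233269599
18-30,female,14.818355640535373,486.6156787762906
30-60,female,8.126195028680687,845.6022944550668
60+,female,9.082217973231357,658.4608030592734
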