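12
method=HF/STO-3G relaxed_max_force=1.27e-09 energy=-227.891358364857 source=rdmlearn_engine
C    1.3867925557  0.0000000000 -0.0000000000
C    0.6933962777  1.2009975829  0.0000000000
C   -0.6933962777  1.2009975829 -0.0000000000
C   -1.3867925557 -0.0000000000  0.0000000000
C   -0.6933962777 -1.2009975829 -0.0000000000
C    0.6933962777 -1.2009975829  0.0000000000
H    2.4694047759 -0.0000000000 -0.0000000000
H    1.2347023880  2.1385672682  0.0000000000
H   -1.2347023880  2.1385672682 -0.0000000000
H   -2.4694047759  0.0000000000 -0.0000000000
H   -1.2347023880 -2.1385672682  0.0000000000
H    1.2347023880 -2.1385672682 -0.0000000000
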