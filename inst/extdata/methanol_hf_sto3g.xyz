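6
method=HF/STO-3G relaxed_max_force=8.14e-08 energy=-113.549192487564 source=rdmlearn_engine
C   -0.0713793389  0.6711313101 -0.0000000000
O    0.0405780808 -0.7574909365  0.0000000000
H    0.9397879189  1.0820236353  0.0000000000
H   -0.5919352052  1.0483665089  0.8864979875
H   -0.5919352052  1.0483665089 -0.8864979875
H   -0.9002162505 -1.0692970267  0.0000000000
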