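3
method=HF/6-31G relaxed_max_force=9.51e-09 energy=-75.9853591692631 source=rdmlearn_engine
O    0.0000000000  0.0000000000  0.0823973171
H    0.0000000000  0.7851664981 -0.4517486585
H   -0.0000000000 -0.7851664981 -0.4517486585
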