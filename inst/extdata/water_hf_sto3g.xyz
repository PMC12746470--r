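3
method=HF/STO-3G relaxed_max_force=1.5e-08 energy=-74.9659007855026 source=rdmlearn_engine
O    0.0000000000 -0.0000000000  0.1501681464
H   -0.0000000000  0.7580806642 -0.4856340732
H   -0.0000000000 -0.7580806642 -0.4856340732
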