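# Conventional MPRAGE protocol (standard clinical parameters)
name: conventional
te_ms: 1.9
tr_ms: 4.2
ti_ms: 1000.0
shot_interval_ms: 3000.0
flip_deg: 7.0
inv_efficiency: -1.0
n_echoes_per_shot: 307
ti_convention: train_centre
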