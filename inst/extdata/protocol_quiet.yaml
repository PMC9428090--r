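# Quiet MPRAGE protocol (silent 20 kHz readout gradient variant)
name: quiet
te_ms: 8.9
tr_ms: 17.6
ti_ms: 1000.0
shot_interval_ms: 3000.0
flip_deg: 13.0
inv_efficiency: -1.0
n_echoes_per_shot: 107
ti_convention: train_centre
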