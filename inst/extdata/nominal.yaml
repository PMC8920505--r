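# Nominal walker condition: V = 0.44 sqrt(gL), S = 0.79 L, b = 0.075 L
body_mass: 1
leg_length: 1
gravity: 1
step_length: 0.79
midstance_speed: 0.44
step_height: 0.075
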