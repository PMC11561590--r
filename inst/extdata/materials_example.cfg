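Material: solution
Phase: 1
Density: 960
Heat_capacity: 2300
Conductivity: 2.0

Material: solution
Melt_temperature_C: -2.0
Transition_half_width: 0.5
Latent_heat: 207000

Material: skin
Phase: 2
Young_modulus: 5e5
Poisson: 0.45
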