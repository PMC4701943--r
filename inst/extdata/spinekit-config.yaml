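# example configuration; every key is optional and defaults to the values
# shown here
biophysics:
  cable: {Cm: 1.0, Ri: 100.0, Rm: 20000.0, Em: -70.0}
  synapse: {tau_syn: 2.0, Esyn: 0.0, gbar_density: 132.0, onset: 0.0}
  integrator: {dt: 1.0, duration: 50.0}
  coupling: symmetric
  parent: {diameter: 3.0, length: 20.0}
morphometry:
  n_stations: 32
  neck_frac: 0.7
  head_min_diameter: 0.43
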