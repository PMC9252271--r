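# Connor-Stevens point-neuron parameters (canonical published set).
# Point-neuron convention: conductances mS/cm^2, potentials mV,
# capacitance uF/cm^2, currents uA/cm^2 with unit membrane area.
capacitance: 1.0
g_na: 120.0
e_na: 55.0
g_k: 20.0
e_k: -72.0
g_a: 47.7
e_a: -75.0
g_leak: 0.3
e_leak: -17.0
v_init: -68.0
spike_threshold: 0.0   # mV, upward crossing
spike_lockout: 2.0     # ms, minimum inter-spike interval
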