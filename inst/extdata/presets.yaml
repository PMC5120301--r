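# Parameter presets for the thalamocortical field model.
# Sections per preset: model (constants), stimulus (reference perturbation
# settings), simulation (integration defaults).
presets:
  taylor2016-default:
    version: 1
    model:
      eps1: -0.35
      eps2: -3.4
      eps3: -4.4
      eps4: -2.0
      eps5: -5.0
      tau1: 26.0
      tau2: 32.5       # 26 * 1.25
      tau3: 0.13       # 26 * 0.005, the slow (GABA-B like) population
      tau4: 2.6        # 26 * 0.1
      tau5: 2.6        # 26 * 0.1
      k1: 1.8
      k2: 1.5
      k3: 0.03
      k4: 1.0
      k5: 4.0
      k6: 0.03
      k7: 3.0
      k8: 1.5
      k9: 0.6
      k10: 3.0
      k11: 0.2
      k12: 10.5
      k13: 3.0
      nu: 2.5e+05
      alpha: 2.8
      beta: 0.5
    stimulus:
      direction: -1
      mode: jump
      initiation: 0.3
      termination: 0.2
      t_initiation: 20.0
      t_termination: 35.0
    simulation:
      dt: 0.001
      duration: 20.0
      transient: 5.0
      initial_state: [0.1724, 0.1787, 0.1803, -0.0818, 0.2775]
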