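compartments:
  HH:
    params:
      A: 0.01
      Cm: 10
    state:
      Ca: 0.050000000000000003
      V: -60
    conductances:
      Kd:
        type: Kd
        params:
          E: -80
          gbar: 300
        state:
          m: 0.017252877733533435
      Leak:
        type: Leak
        params:
          E: -50
          gbar: 1
      NaV:
        type: NaV
        params:
          E: 50
          gbar: 1000
        state:
          h: 0.89499941497973523
          m: 0.0014689474459206771
simulation:
  dt: 0.050000000000000003
  t_end: 1000
  solver: exp_euler

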