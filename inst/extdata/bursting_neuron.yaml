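compartments:
  AB:
    params:
      A: 0.062799999999999995
      Cm: 10
    state:
      Ca: 0.050000000000000003
      V: -60
    conductances:
      ACurrent:
        type: ACurrent
        params:
          E: -80
          gbar: 500
        state:
          h: 0.65309079214139842
          m: 0.022530107995424174
      CaS:
        type: CaS
        params:
          E: 30
          gbar: 60
        state:
          h: 0.5
          m: 0.034445195666211167
      CaT:
        type: CaT
        params:
          E: 30
          gbar: 25
        state:
          h: 0.99377370008585553
          m: 0.010257410848182861
      HCurrent:
        type: HCurrent
        params:
          E: -20
          gbar: 0.10000000000000001
        state:
          m: 0.15886910488091516
      KCa:
        type: KCa
        params:
          E: -80
          gbar: 50
        state:
          m: 0.0012254571656942156
      Kd:
        type: Kd
        params:
          E: -80
          gbar: 1000
        state:
          m: 0.017252877733533435
      Leak:
        type: Leak
        params:
          E: -50
          gbar: 0.099000000000000005
      NaV:
        type: NaV
        params:
          E: 50
          gbar: 1000
        state:
          h: 0.89499941497973523
          m: 0.0014689474459206771
    mechanisms:
      CalciumMech:
        type: CalciumMech
        params:
          Ca_0: 0.050000000000000003
          Ca_out: 3000
          T: 11
          f: 14.960000000000001
          tau_Ca: 200
simulation:
  dt: 0.050000000000000003
  t_end: 1000
  solver: exp_euler

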