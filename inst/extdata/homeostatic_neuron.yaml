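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
          gbar: 10
        state:
          h: 0.65309079214139842
          m: 0.022530107995424174
      CaS:
        type: CaS
        params:
          E: 30
          gbar: 10
        state:
          h: 0.5
          m: 0.034445195666211167
      CaT:
        type: CaT
        params:
          E: 30
          gbar: 10
        state:
          h: 0.99377370008585553
          m: 0.010257410848182861
      HCurrent:
        type: HCurrent
        params:
          E: -20
          gbar: 10
        state:
          m: 0.15886910488091516
      KCa:
        type: KCa
        params:
          E: -80
          gbar: 10
        state:
          m: 0.0012254571656942156
      Kd:
        type: Kd
        params:
          E: -80
          gbar: 10
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
          gbar: 10
        state:
          h: 0.89499941497973523
          m: 0.0014689474459206771
    mechanisms:
      ACurrent_ctrl:
        type: IntegralController
        target: ACurrent
        params:
          Ca_target: 65
          tau_g: 5000
          tau_m: 4000
        state:
          mRNA: 10
      CaS_ctrl:
        type: IntegralController
        target: CaS
        params:
          Ca_target: 65
          tau_g: 5000
          tau_m: 33333.333333333336
        state:
          mRNA: 10
      CaT_ctrl:
        type: IntegralController
        target: CaT
        params:
          Ca_target: 65
          tau_g: 5000
          tau_m: 80000
        state:
          mRNA: 10
      CalciumMech:
        type: CalciumMech
        params:
          Ca_0: 0.050000000000000003
          Ca_out: 3000
          T: 11
          f: 14.960000000000001
          tau_Ca: 200
      HCurrent_ctrl:
        type: IntegralController
        target: HCurrent
        params:
          Ca_target: 65
          tau_g: 5000
          tau_m: 20000000
        state:
          mRNA: 10
      KCa_ctrl:
        type: IntegralController
        target: KCa
        params:
          Ca_target: 65
          tau_g: 5000
          tau_m: 40000
        state:
          mRNA: 10
      Kd_ctrl:
        type: IntegralController
        target: Kd
        params:
          Ca_target: 65
          tau_g: 5000
          tau_m: 2000
        state:
          mRNA: 10
      NaV_ctrl:
        type: IntegralController
        target: NaV
        params:
          Ca_target: 65
          tau_g: 5000
          tau_m: 2000
        state:
          mRNA: 10
simulation:
  dt: 0.050000000000000003
  t_end: 1000
  solver: exp_euler

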