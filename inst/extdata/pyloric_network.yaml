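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
          gbar: 0
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
  LP:
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
          gbar: 200
        state:
          h: 0.65309079214139842
          m: 0.022530107995424174
      CaS:
        type: CaS
        params:
          E: 30
          gbar: 40
        state:
          h: 0.5
          m: 0.034445195666211167
      HCurrent:
        type: HCurrent
        params:
          E: -20
          gbar: 0.5
        state:
          m: 0.15886910488091516
      KCa:
        type: KCa
        params:
          E: -80
          gbar: 0
        state:
          m: 0.0012254571656942156
      Kd:
        type: Kd
        params:
          E: -80
          gbar: 250
        state:
          m: 0.017252877733533435
      Leak:
        type: Leak
        params:
          E: -50
          gbar: 0.29999999999999999
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
  PY:
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
          gbar: 20
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
          gbar: 0.5
        state:
          m: 0.15886910488091516
      KCa:
        type: KCa
        params:
          E: -80
          gbar: 0
        state:
          m: 0.0012254571656942156
      Kd:
        type: Kd
        params:
          E: -80
          gbar: 1250
        state:
          m: 0.017252877733533435
      Leak:
        type: Leak
        params:
          E: -50
          gbar: 0.10000000000000001
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
synapses:
- type: Cholinergic
  pre: AB
  post: LP
  params:
    Delta: 5
    E_syn: -80
    V_half: -35
    gbar: 30
    k_minus: 0.01
  state:
    s: 0
- type: Glutamatergic
  pre: AB
  post: LP
  params:
    Delta: 5
    E_syn: -70
    V_half: -35
    gbar: 30
    k_minus: 0.025000000000000001
  state:
    s: 0
- type: Cholinergic
  pre: AB
  post: PY
  params:
    Delta: 5
    E_syn: -80
    V_half: -35
    gbar: 3
    k_minus: 0.01
  state:
    s: 0
- type: Glutamatergic
  pre: AB
  post: PY
  params:
    Delta: 5
    E_syn: -70
    V_half: -35
    gbar: 10
    k_minus: 0.025000000000000001
  state:
    s: 0
- type: Glutamatergic
  pre: LP
  post: AB
  params:
    Delta: 5
    E_syn: -70
    V_half: -35
    gbar: 30
    k_minus: 0.025000000000000001
  state:
    s: 0
- type: Glutamatergic
  pre: LP
  post: PY
  params:
    Delta: 5
    E_syn: -70
    V_half: -35
    gbar: 1
    k_minus: 0.025000000000000001
  state:
    s: 0
- type: Glutamatergic
  pre: PY
  post: LP
  params:
    Delta: 5
    E_syn: -70
    V_half: -35
    gbar: 30
    k_minus: 0.025000000000000001
  state:
    s: 0
simulation:
  dt: 0.050000000000000003
  t_end: 1000
  solver: exp_euler

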