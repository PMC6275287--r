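# neurodyn

Conductance-based neuron and network simulation in R, for computational
neuroscientists and electrophysiologists who want small, fully inspectable
models — single cells, homeostatically regulated cells, and small named
circuits — with reproducible, hash-audited numerics.

Models are hierarchical trees of named components. Each compartment *i*
obeys

```
C_i dV_i/dt = -Σ_j I_j,      I_j = ḡ_j m_j^p h_j^q (V_i - E_j) A_i
```

with gating variables relaxing as `τ_m(V) dm/dt = m∞(V) - m` (and likewise
for *h*). The package provides:

* a **channel library** (NaV, CaT, CaS, ACurrent, KCa, Kd, HCurrent, Leak;
  classic stomatogastric kinetics) plus registration of custom channels
  from plain R gating functions;
* **mechanisms**: calcium influx/buffering with Nernst-tracked reversal,
  and calcium-error integral control of conductance densities
  (homeostatic regulation);
* **graded chemical synapses** (glutamatergic, cholinergic kinetics) and
  electrical synapses;
* **fixed-step integrators** in compiled code: exponential Euler
  (default; networks, mechanisms, voltage clamp), classical RK4 (single
  compartments), and an implicit Crank–Nicolson solver for unbranched
  cables;
* a **protocol layer**: f–I curves, in-silico voltage clamp with
  sigmoid^n activation-curve recovery, spike/burst detection,
  dominant-current labeling, a (V, dV/dt) occupancy-histogram trace cost,
  and parameter sweeps;
* **reproducibility plumbing**: canonical serialization of every
  parameter and state, named snapshots with bit-exact reset, MD5
  structural/full hashes, YAML model configs, and CSV traces stamped with
  the generating model's hash.

## Worked example

Build the classic three-channel spiking neuron, measure its f–I curve,
then recover the delayed rectifier's activation curve from a simulated
voltage-clamp experiment:

```r
library(neurodyn)

hh <- make_fixture("hh_neuron")
hh
#> <model_tree> 1 compartment(s), 0 synapse(s), 5 dynamic state variable(s)
#>   HH: NaV, Kd, Leak

fi_curve(hh, c(0, 0.1, 0.2, 0.3), t_end = 1500)
#>     I rate
#> 1 0.0    0
#> 2 0.1   19
#> 3 0.2   41
#> 4 0.3   54
```

The cell is quiescent without input and fires tonically (41 Hz) at
0.2 nA. Now clamp a Kd-only compartment across −80..+50 mV, convert
asymptotic clamp currents to conductances, and fit `sigmoid^n`:

```r
recover_activation("Kd")
#> <activation_fit> best exponent n = 4 (V_half = -12.30 mV, k = 11.80 mV)
#>   residual sum of squares by exponent:
#>        n1        n2        n3        n4        n5        n6        n7        n8
#> 4.843e-03 6.395e-04 7.485e-05 1.537e-30 2.800e-05 7.848e-05 1.305e-04 1.785e-04
```

The fourth-power activation is identified exactly, and the fitted
midpoint/slope are the channel's true parameters. Bursting and network
fixtures work the same way:

```r
bu <- make_fixture("bursting_neuron")
tr <- integrate_model(bu, t_end = 10000, dt = 0.05, out_dt = 0.25)
bursts <- detect_bursts(spike_times(tr))
nrow(bursts); mean(diff(bursts$onset))
#> [1] 18
#> [1] 581.2  # ms burst period
```

Every model carries two MD5 hashes — structure+equations, and
structure+equations+all values:

```r
structural_hash(hh)  #> "872c57db5d3352e65eb76a89fd2c17bb"
full_hash(hh)        #> "750b5b279392d3c8998843c0c2fb99b4"
```

`snapshot()` / `restore_snapshot()` bookmark the full serialized state;
re-integration after a restore is bit-identical. See
`vignettes/neurodyn-methods.Rmd` for the model equations, numerical
choices, and fixture definitions, and `inst/extdata/*.yaml` for the
canonical config of every fixture.

## Command line

A thin CLI ships in `inst/cli/neurodyn`:

```sh
inst/cli/neurodyn simulate inst/extdata/hh_neuron.yaml --t-end 2000 \
    --iext HH=0.2 --out trace.csv
inst/cli/neurodyn clamp-recover --channel Kd
inst/cli/neurodyn list-channels
```

Exit codes: 0 success, 2 validation error, 3 numerical failure.

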