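# spindec

Simulation of electron-spin decoherence in proton spin baths, with and
without microwave irradiation, including methyl-group tunnelling.

## What it does, and for whom

In pulsed EPR and dynamic nuclear polarization, the phase memory of an
unpaired electron — for instance in a trityl radical used as a spin label
or polarizing agent — is limited by the surrounding proton spins. `spindec`
simulates the two standard observables for a central electron spin
(S = 1/2) coupled to N proton spins (I = 1/2):

* the **bare-spin** Hahn echo decay, `(pi/2) - T/2 - (pi) - T/2 - echo`,
  whose time constant is the phase-memory time `Tm`;
* the **dressed-spin** primary echo during a spin lock of amplitude `w1`,
  generated by a `pi/2 - T/2 - pi - T/2 - pi/2` sequence of
  phase-modulation (PM) pulses, whose decay defines `T2rho`. Driving the
  electron decouples the hyperfine interaction, so dressed-spin coherence
  generally outlives bare-spin coherence.

It is intended for magnetic-resonance spectroscopists exploring how bath
composition, methyl tunnelling, drive amplitude and simulation method shape
these decays.

## Model

Per field orientation, the cluster Hamiltonian (rotating frame, nuclear
Zeeman dropped) is

    H = OmegaS Sz + sum_n (An Sz Inz + Bnx Sz Inx + Bny Sz Iny)
      + sum_{k<l} [ wzz,kl Ikz Ilz - (wnn,kl/4)(Ik+ Il- + Ik- Il+) ]
      + w1 Sx

with hyperfine components `(An, Bnx, Bny)` projected from 3x3 tensors, and
pair couplings that fold the methyl tunnel splitting `wt` into an exchange
coupling: `wzz = wdd - 2 wt/3`, `wnn = wdd + 4 wt/3` within a methyl group,
`wzz = wnn = wdd` otherwise. A hindered-rotor solver converts threefold
rotation barriers `V3` into tunnel splittings.

Decay traces over the full bath are assembled by four engines:

| engine | idea | scope |
|---|---|---|
| `appa` | product of analytical two-proton echo factors | bare mode |
| `cce`  | cluster correlation expansion truncated at order o | both modes |
| `pcce` | partial CCE: disjoint size-s clusters plus all supercluster correlations of u clusters | both modes |
| `cf`   | plain cluster factorization (pCCE with u = 1) | both modes |

Density operators are propagated via the eigendecomposition of each
Hermitian cluster Hamiltonian, with whole sequences evaluated in the
eigenbasis for numerical stability. Powder averages run on deterministic
hemispherical grids with `2k(k-1)+1` orientations (9 knots = 145
orientations); orientations whose normalized signal becomes negative or
exceeds 1.1 are rejected and the rejected fraction is reported. Synthetic
methyl-group and trityl-like geometries with point-dipole hyperfine tensors
are generated by the package; no external data are required.

## Worked example

```r
library(spindec)

# a 12-proton trityl-like core: 4 methyl groups, two tunnel classes
sys <- make_trityl_like(n_methyls = 4, ring_radius = 4.6,
                        tunnel_inner_kHz = 4.8, tunnel_outer_kHz = 54.5,
                        seed = 1)
print(sys)
#> <spin_system> 12 proton(s), 4 methyl group(s)
#>   tunnel splittings [kHz]: 4.8, 54.5, 4.8, 54.5
#>   offset sigma: 5.1 MHz

# bare-spin Hahn echo decay, CCE-2, 5-orientation powder grid
sim <- simulate_decoherence(sys, times = seq(0, 28, 0.5),
                            engine = "cce", order = 2, knots = 2)
summary(sim)
#> Powder-averaged bare-spin decoherence (engine cce, order 2)
#>   protons: 12, methyl groups: 4
#>   grid: 2 knots, 5 orientations, rejected 0.0%
#>   time axis: 0 .. 28 us (57 points)
#>   1/e decay time: 8.76 us

# dressed-spin echo under a 100 MHz spin lock, cluster factorization
simd <- simulate_decoherence(sys, times = seq(0.2, 28, 0.5),
                             engine = "cf", mode = "dressed",
                             partition = methyl_partition(sys), knots = 2)
cat(sprintf("bare signal at 28 us:    %.3f\n", tail(sim$trace$values, 1)))
#> bare signal at 28 us:    0.342
cat(sprintf("dressed signal at 28 us: %.3f\n", tail(simd$trace$values, 1)))
#> dressed signal at 28 us: 0.658
```

The bare echo has decayed through 1/e after about 9 us, while the
spin-locked (dressed) echo of the same system is still at 0.66 after
28 us — hyperfine decoupling at work. `plot(sim)` draws the trace.

The rotor solver connects barriers to tunnel splittings:

```r
tunnel_splitting(rotor_model(15.8))   # kJ/mol in, kHz out
#> [1] 55.14073
```

A thin command-line front end wraps the same functions:

    Rscript inst/cli/spindec fixture --n-methyls 12 --out sys.json
    Rscript inst/cli/spindec cce --system sys.json --order 2 --out trace.csv
    Rscript inst/cli/spindec barrier2tunnel --v3 15.8,20
    Rscript inst/cli/spindec grid --knots 9 --out grid.csv

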