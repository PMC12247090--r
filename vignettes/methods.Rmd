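---
title: "Simulating bare- and dressed-spin electron decoherence in proton baths"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Simulating bare- and dressed-spin electron decoherence in proton baths}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(spindec)
```

## The physical problem

A single electron spin (S = 1/2), such as the unpaired electron of a trityl
radical, loses phase coherence through its coupling to the surrounding bath
of proton spins. Two observables are simulated here:

* **Bare-spin decoherence** `Tm`: decay of a two-pulse Hahn echo,
  `(pi/2) - T/2 - (pi) - T/2 - echo`, as the total evolution time `T` is
  incremented. The refocusing pulse cancels static offsets and secular
  hyperfine fields, so the decay is dominated by dynamics inside the
  nuclear bath: proton flip-flops driven by homonuclear dipolar couplings,
  and tunnelling of methyl groups.
* **Dressed-spin decoherence** `T2rho`: during continuous microwave
  irradiation of amplitude `w1` (spin lock along `+x`), the driven electron
  behaves as a new two-level system — a *dressed spin* — quantized along the
  effective field and split by roughly `w1`. Phase modulation (PM) of the
  lock field at frequency `w1` acts as a resonant pulse on the dressed
  spin, so a `pi/2 - T/2 - pi - T/2 - pi/2` PM sequence generates a primary
  echo whose decay defines `T2rho`. Strong irradiation decouples the
  hyperfine interaction, so the dressed spin decoheres more slowly than the
  bare spin.

## Spin Hamiltonian

In the rotating frame, with the nuclear Zeeman term dropped (it commutes
with all retained terms and the initial states used), the working
Hamiltonian for a cluster of protons is

```
H = OmegaS Sz + sum_n An Sz Inz + Bnx Sz Inx + Bny Sz Iny
  + sum_{k<l} wzz,kl Ikz Ilz
  - sum_{k<l} (wnn,kl / 4) (Ik+ Il- + Ik- Il+)
  + w1 Sx ,
```

where `OmegaS` is the electron resonance offset, `(An, Bnx, Bny)` are the
secular and pseudo-secular hyperfine components obtained by projecting each
proton's 3x3 hyperfine tensor onto the field orientation, and the pair
couplings combine the secular homonuclear dipolar coupling `wdd` with
methyl tunnelling. Tunnelling of a methyl group with tunnel splitting `wt`
is represented as an exchange coupling between its three protons, which
shifts the pair terms to

```
wzz = wdd - 2 wt / 3 ,      wnn = wdd + 4 wt / 3
```

for pairs inside one methyl group, while all other pairs keep
`wzz = wnn = wdd`. This assumes negligible rotor-rotor coupling and the
high-temperature limit for the tunnel reservoir; no temperature dependence
is implemented. The frame transformation that merges `(Bnx, Bny)` into a
single component is deliberately not applied, because it complicates the
nuclear-nuclear coupling terms; pseudo-secular hyperfine terms are kept in
all numerical work and omitted only in the analytical pair expressions.

Conventions: all interface quantities are ordinary frequencies — MHz for
`An`, `Bn`, `OmegaS` and `w1`, kHz for `wdd`, `wzz`, `wnn` and tunnel
splittings — with distances in angstrom and times in microseconds.
Internally everything is converted once to angular frequency (rad/us),
which removes the recurring source of factor-of-2-pi errors. Operators are
built by Kronecker products with the electron first; each spin is ordered
`|alpha>, |beta>`.

An orientation `(theta, phi)` gives the direction of the static field in
the molecular frame; the projection uses the rotation with ZYZ Euler angles
`(phi, theta, 0)`. Only the field direction enters the retained
Hamiltonian, so the third Euler angle is irrelevant, and inversion symmetry
restricts grids to the upper hemisphere.

## Dressed-frame analytics

Neglecting nuclear-nuclear couplings, each nuclear spin configuration `c`
contributes a hyperfine field `dw_c = sum_n An m_n` and tilts the electron
quantization axis to

```
theta_c = atan2(w1, OmegaS + dw_c) ,
```

implemented with the two-argument arctangent so the angle passes
continuously through 90 degrees at resonance. The residual splitting of the
electron transitions in the configuration/complement pair is

```
Aeff,c = sqrt((OmegaS + dw_c)^2 + w1^2) - sqrt((OmegaS - dw_c)^2 + w1^2) ,
```

which vanishes on resonance — the hyperfine decoupling effect. The locked
("slow") fraction of the initial `-Sx` magnetization is
`f_slow = mean_c sin(theta_c)`, enumerated exactly up to 20 protons and
Monte-Carlo sampled beyond. At `w1 = 100` MHz and a combined offset plus
hyperfine field of 10 MHz the tilt deviates from 90 degrees by 5.71 degrees
and about 0.5 % of the magnetization is unlocked; these numbers are the
desk-scale anchors of the test suite.

## Sequences and numerical propagation

Bare-mode pulses are ideal (instantaneous electron rotations); the echo
observable is the real part of the refocused coherence, normalized at
`T = 0`. Taking the real part rather than the modulus keeps sign
information, which the instability-rejection rule below needs.

Dressed-mode simulations start from `-Sx` (an ideal `pi/2` pulse applied to
`-Sz`), evolve under the full Hamiltonian including the drive for a settle
delay (default 0.996 us, matching the experimental timing), and then apply
the PM echo sequence. Two PM pulse models are provided:

* **ideal** (default): instantaneous rotations `exp(-i beta Sz)` about the
  rotating-frame z axis, which is perpendicular to the lock axis `x`. The
  fast carrier precession about `x` cancels over the echo, so this is the
  hard-pulse limit.
* **explicit**: piecewise-constant propagation of the physically modulated
  drive `w1 (cos(phi(t)) Sx + sin(phi(t)) Sy)` with
  `phi(t) = aPM cos(2 pi w1 t)`, time steps of at most `1/(20 w1)`, and
  pulse lengths set by the first-harmonic dressed nutation frequency
  `w1 J1(aPM)` (default `aPM = 0.3`). On small systems the explicit model
  reproduces the ideal traces to a few parts in a thousand and shows the
  expected small echo-amplitude loss from finite pulse duration; it exists
  to validate the ideal model, not for production runs.

The echo is `<Sx>` after the final PM pulse, normalized at the smallest
simulated `T` — after, not before, any averaging over the offset
distribution, so that packets keep their relative amplitudes.

All propagation uses the eigendecomposition of the Hermitian cluster
Hamiltonian: `U(t) = V exp(-i Lambda t) V'`, with whole sequences evaluated
in the eigenbasis (free evolutions become elementwise phase factors; each
pulse costs two matrix multiplications per time point). This is both faster
and markedly more stable at long evolution times than general
matrix-exponential algorithms, which matters because expansion engines
divide many nearly-equal signals.

## Expansion engines

For a bath of `N` protons, a direct simulation has dimension `2^(N+1)` and
is feasible only for small clusters. Four engines assemble the full decay
from cluster simulations; all work per orientation and are averaged
afterwards:

* **APPA** — the product over all proton pairs of the analytical two-proton
  echo factor
  `W_kl(T) = 1 - (3/2) l - (l/2) cos(w T) + 2 l cos(w T/2)` with modulation
  depth `l = dA^2 wnn^2 / (dA^2 + wnn^2)^2` (maximal, 1/4, when the
  hyperfine difference `dA` matches the flip-flop coupling `wnn`) and
  zero-quantum frequency `w = sqrt(dA^2 + wnn^2)/2`. Bare mode only; in the
  high-field secular limit it is identical to CCE-2, which the suite
  verifies to 1e-6 on random systems.
* **CCE-o** — all clusters up to size `o`; every cluster signal is divided
  by the product of its subcluster contributions (memoized in increasing
  size) and the empty-bath signal, and the surviving "tilde" factors are
  multiplied together. At `o = N` this telescopes to the direct simulation
  exactly, which the suite checks to 1e-6 in both modes.
* **pCCE(s, o)** — the bath is partitioned into disjoint clusters of size
  `s` (for methyl-bearing systems the natural partition is by methyl
  group); each cluster signal is corrected for the empty-bath signal, and
  inter-cluster correlations are added for every supercluster of `u = o/s`
  clusters (`choose(M, u)` of them). Equal cluster sizes are enforced; the
  partitioning itself is user-supplied because no optimal algorithm is
  established.
* **CF** — plain cluster factorization, the `u = 1` limit of pCCE; exact
  when inter-cluster couplings vanish.

Division of nearly-zero signals makes high-order CCE numerically fragile.
Two safeguards mirror this: any division whose denominator falls below a
floor (default 1e-10) flags the cluster and marks the trace unstable
rather than patching it; and at the powder level, orientations whose
normalized signal becomes negative or exceeds 1.1 inside the inspection
window are discarded, with the rejected fraction reported. The floor value
is this package's choice; the orientation-level thresholds are the
established ones. No distance cutoff is applied when enumerating clusters
— remote couplings matter for dressed-spin decoherence — though the floor
and partition arguments allow experimentation.

The empty-bath reference deserves a note. Within one orientation and one
offset, the expansions use the empty-bath trace at that same offset, which
makes the telescoping identities exact. The *distribution* of resonance
offsets (Gaussian; default width set so the FWHM is 12 MHz, a typical
trityl EPR linewidth at Q band) is handled one level up:
`w_empty()` averages the raw empty-bath echo over Gauss-Hermite nodes, and
`simulate_decoherence(offset_nodes = ...)` applies the same quadrature to
the assembled traces. Averaging raw amplitudes before normalizing captures
the echo loss from imperfect locking of off-resonant packets.

## Powder averaging

`orientation_grid(k)` builds `k` equally spaced rings from the pole to the
equator with `4(i-1)` points on ring `i` (one at the pole), i.e.
`2k(k-1)+1` orientations — 145 at 9 knots, 85 at 7, 1013 at 23, matching
the grid sizes used in practice for this problem class. Weights are the
solid angles of the latitude bands around each ring, split equally within
the ring and normalized; the reference grids' exact weights are not
published, so sub-percent differences from other implementations are
expected. The quadrature integrates `1 - 3 cos^2(theta)` to zero at
`O(k^-2)`, which the suite checks.

## Tunnel splittings from rotation barriers

`tunnel_splitting()` solves the one-dimensional hindered-rotor problem
`H = -B d^2/dphi^2 + V3 [cos(3 phi) + 1]/2` in a plane-wave basis
partitioned by threefold symmetry (A block: `m = 0 mod 3`; E block:
`m = 1 mod 3`) and returns the ground-state A-E splitting. The default
rotational constant, `B = 158.4` GHz, follows from three protons at a C-H
distance of 1.09 angstrom with tetrahedral geometry; the free-rotor limit
`V3 = 0` returns exactly `B`. Barriers of 15.8 and 20.0 kJ/mol map to 55.1
and 4.7 kHz, consistent with the 54.5 and 4.8 kHz quoted for outer and
inner methyl groups of the Finland trityl core; exact agreement depends on
the rotor geometry behind `B`, so only order-of-magnitude consistency is
promised. Convergence is tested by doubling the basis; because the
splitting is a kHz-scale difference of eigenvalues of order 1e5 GHz, the
relative criterion is combined with a floating-point noise floor
proportional to the spectral scale. The barrier-scan fit phase only shifts
the origin of the torsion angle and never affects the splitting. An
independent finite-difference Bloch-wave solver serves as the oracle in
the tests (1-2 % agreement).

## Synthetic spin systems

`make_methyl()` builds an ideal methyl fragment (tetrahedral H-C-axis
angle, protons 120 degrees apart, H-H distance 1.78 angstrom at
`r_CH = 1.09`); `make_trityl_like()` arranges an even number of such
fragments on a ring around the electron with radially outward axes,
alternating inner/outer tunnel splittings, and alternating out-of-plane
displacements `+-z_split` that mirror the geminal-dimethyl motif and keep
fragments from clashing; `make_random_bath()` scatters protons in a
spherical shell. All hyperfine tensors are point-dipole
(`T = d_eH (3 n n' - 1)/r^3`, traceless and axial), valid beyond about 2
angstrom from the electron and enforced as such.

What the generator does *not* emulate: spin density delocalized over the
radical (DFT-quality tensors have isotropic contributions and non-axial
anisotropy), conformational distributions of side groups, matrix protons,
and distributions of tunnel splittings in glassy matrices. Passing tests
therefore demonstrate correctness of the machinery — couplings, dynamics,
expansions, averaging — on geometrically faithful model systems, not
quantitative reproduction of measured decay curves for a particular
radical, which requires computed tensors for that molecule.

## Numerical choices and degenerate inputs

* Hermiticity of assembled Hamiltonians is asserted at 1e-10; propagation
  preserves traces to the same level, and imaginary residues above 1e-7 in
  echo signals raise a warning (a real trace is a sensitive bug detector).
* Antisymmetric parts of input hyperfine tensors are discarded with a
  warning; coincident protons (below 0.5 angstrom) and protons inside the
  point-dipole validity radius are errors, not warnings.
* Normalization at `T = 0` (bare) or the smallest `T` (dressed) assumes a
  non-vanishing reference amplitude; dressed time axes should start at a
  small positive settle-consistent value such as 0.2 us.
* `w1` should exceed the largest secular coupling by a wide margin in
  dressed mode; a warning is issued when `max |An| > w1/5`.

## Problem sizes used in the shipped checks

The test suite and the acceptance script run entirely on synthetic
fixtures at desk scale: full-order oracle equivalences on 3-4 proton
systems (dimensions 16-32), APPA/CCE-2 equivalence on random 2-4 proton
secular systems, and an end-to-end 12-proton, 4-methyl powder run at 5
orientations with CCE orders 1-3 plus a pCCE(3,6) cross-check, chosen so
the whole suite completes in well under a minute. Production-scale runs
(36 protons, pCCE(3,9), 85-1013 orientations) use exactly the same code
path through `simulate_decoherence()`; only cluster sizes and grids grow.

## Known limitations

* Dressed-spin CCE does not converge monotonically with order — CCE-3 can
  be worse than CCE-2 — which is a property of the method for dressed
  spins, not of this implementation; pCCE over a physically motivated
  partition is the intended tool there.
* Only ideal (infinitely hard) microwave pulses are available for the bare
  sequence; finite pulse effects, instantaneous diffusion, electron-
  electron couplings and T1 processes are out of scope.
* Nuclei other than protons are not modelled (deuterated-matrix limit);
  the detection block after the spin lock is not simulated — the echo
  amplitude is read out directly.
* Tunnel splittings are temperature-independent (high-temperature
  reservoir assumption) and rotor-rotor coupling is neglected.
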