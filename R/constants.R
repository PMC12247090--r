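# Physical constants (CODATA 2018) and derived dipolar prefactors.
# Interface units throughout the package are ordinary frequencies
# (MHz for hyperfine / drive / offset quantities, kHz for nuclear-nuclear
# and tunnel couplings), angstrom for distances and microseconds for time.
# Internally, Hamiltonians are assembled in angular frequency units of
# rad/us, so that exp(-i*H*t) takes t directly in us.

.const <- local({
  mu0 <- 4 * pi * 1e-7          # vacuum permeability, T^2 m^3 / J
  hbar <- 1.054571817e-34       # J s
  h <- 6.62607015e-34           # J s
  gammaH <- 2.6752218744e8      # proton gyromagnetic ratio, rad s^-1 T^-1
  gammaE <- 1.76085963023e11    # electron gyromagnetic ratio, rad s^-1 T^-1
  NA_ <- 6.02214076e23
  mH <- 1.67262192369e-27       # proton mass, kg

  # homonuclear 1H-1H dipolar constant, ordinary frequency: kHz A^3
  # mu0 gammaH^2 hbar / (4 pi) / (2 pi), evaluated at r in angstrom
  d_HH_kHz_A3 <- mu0 / (4 * pi) * gammaH^2 * hbar / 1e-30 / (2 * pi) / 1e3

  # electron-proton point-dipole constant, MHz A^3
  d_eH_MHz_A3 <- mu0 / (4 * pi) * gammaE * gammaH * hbar / 1e-30 / (2 * pi) / 1e6

  # kJ/mol -> GHz (energy per molecule over h)
  kJmol_to_GHz <- 1000 / NA_ / h / 1e9

  # default methyl-rotor rotational constant B = hbar^2/(2 I) / h in GHz,
  # from three protons at C-H = 1.09 A and tetrahedral H-C-H geometry
  rCH <- 1.09e-10
  rperp <- rCH * sin(acos(-1 / 3))
  I_CH3 <- 3 * mH * rperp^2
  B_CH3_GHz <- hbar^2 / (2 * I_CH3) / h / 1e9

  list(d_HH_kHz_A3 = d_HH_kHz_A3, d_eH_MHz_A3 = d_eH_MHz_A3,
       kJmol_to_GHz = kJmol_to_GHz, B_CH3_GHz = B_CH3_GHz)
})

# angular-frequency conversion helpers (interface value -> rad/us)
.MHz <- function(x) 2 * pi * x
.kHz <- function(x) 2 * pi * x / 1e3

#' Physical constants used by spindec
#'
#' Returns the dipolar prefactors and rotor constants derived from CODATA
#' values: the proton-proton dipolar constant (kHz A^3), the electron-proton
#' point-dipole constant (MHz A^3), the kJ/mol to GHz conversion and the
#' default methyl-rotor rotational constant (GHz).
#'
#' @return Named list of constants.
#' @export
#' @examples
#' spindec_constants()$d_HH_kHz_A3  # approximately 120.1
spindec_constants <- function() .const
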