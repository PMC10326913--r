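# Physical constants and composition tables used throughout the mass engine.
# Monoisotopic atomic masses; the proton mass is the m/z charge carrier and
# 1.003355 Da (C13 - C12) is the isotopologue spacing used for A+k precursors.

PROTON_MASS <- 1.007276
NEUTRON_SPACING <- 1.003355
WATER_MASS <- 18.0105646

.atomic_masses <- c(
  C = 12,
  H = 1.0078250319,
  N = 14.0030740052,
  O = 15.9949146221,
  S = 31.97207069
)

# Natural-abundance isotope distributions per element, indexed by neutron
# offset k = 0, 1, 2, ... relative to the lightest isotope.
.isotope_abundances <- list(
  C = c(0.9893, 0.0107),
  H = c(1 - 0.000115, 0.000115),
  N = c(1 - 0.00364, 0.00364),
  O = c(1 - 0.00038 - 0.00205, 0.00038, 0.00205),
  S = c(1 - 0.0075 - 0.0425, 0.0075, 0.0425)
)

# Elemental composition of amino-acid residues (i.e. minus water).
.residue_compositions <- list(
  G = c(C = 2, H = 3, N = 1, O = 1),
  A = c(C = 3, H = 5, N = 1, O = 1),
  S = c(C = 3, H = 5, N = 1, O = 2),
  P = c(C = 5, H = 7, N = 1, O = 1),
  V = c(C = 5, H = 9, N = 1, O = 1),
  T = c(C = 4, H = 7, N = 1, O = 2),
  C = c(C = 3, H = 5, N = 1, O = 1, S = 1),
  L = c(C = 6, H = 11, N = 1, O = 1),
  I = c(C = 6, H = 11, N = 1, O = 1),
  N = c(C = 4, H = 6, N = 2, O = 2),
  D = c(C = 4, H = 5, N = 1, O = 3),
  Q = c(C = 5, H = 8, N = 2, O = 2),
  K = c(C = 6, H = 12, N = 2, O = 1),
  E = c(C = 5, H = 7, N = 1, O = 3),
  M = c(C = 5, H = 9, N = 1, O = 1, S = 1),
  H = c(C = 6, H = 7, N = 3, O = 1),
  F = c(C = 9, H = 9, N = 1, O = 1),
  R = c(C = 6, H = 12, N = 4, O = 1),
  Y = c(C = 9, H = 9, N = 1, O = 2),
  W = c(C = 11, H = 10, N = 2, O = 1)
)

# Glycan monomer residue compositions (glycosidic-bond water already excluded):
# Hex 162.052824, HexNAc 203.079373, dHex 146.057909, NeuAc 291.095417 Da.
.glycan_monomers <- list(
  Hex    = c(C = 6, H = 10, O = 5),
  HexNAc = c(C = 8, H = 13, N = 1, O = 5),
  dHex   = c(C = 6, H = 10, O = 4),
  NeuAc  = c(C = 11, H = 17, N = 1, O = 8)
)

# Built-in cysteine chemistry. Deltas are signed elemental compositions:
#   NEM cap           +C6H7NO2   (+125.047679 Da) on Cys
#   cysteinylation    +C3H5NO2S  (+119.004099 Da) on Cys (free Cys via S-S)
#   disulfide bond    -H2        (-2.015650 Da) per link
.builtin_modifications <- list(
  NEM = list(
    delta = c(C = 6, H = 7, N = 1, O = 2),
    site = "C"
  ),
  cysteinylation = list(
    delta = c(C = 3, H = 5, N = 1, O = 2, S = 1),
    site = "C"
  )
)

DISULFIDE_DELTA <- c(H = -2)

# Singly charged glycan oxonium ions. HexNAc and HexNAc-Hex follow from the
# monomer residue mass + proton; the 138 ion is the HexNAc secondary fragment.
.oxonium_table <- c(
  "HexNAc" = 204.086649,
  "HexNAc-Hex" = 366.139473,
  "HexNAc_frag138" = 138.055
)
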