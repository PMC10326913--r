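# Independent oracles for the mass engine, deliberately not sharing code with
# the package: literal monoisotopic residue masses (frozen constants) for
# peptide-mass summation, and a full enumeration of isotope assignments for
# small molecules.

.oracle_residue_masses <- c(
  G = 57.02146, A = 71.03711, S = 87.03203, P = 97.05276, V = 99.06841,
  T = 101.04768, C = 103.00919, L = 113.08406, I = 113.08406, N = 114.04293,
  D = 115.02694, Q = 128.05858, K = 128.09496, E = 129.04259, M = 131.04049,
  H = 137.05891, F = 147.06841, R = 156.10111, Y = 163.06333, W = 186.07931
)

oracle_peptide_mass <- function(seq) {
  sum(.oracle_residue_masses[strsplit(seq, "")[[1]]]) + 18.010565
}

# Brute-force aggregated isotope pattern: every atom independently picks an
# isotope; sum offsets, multiply abundances. Tractable for <= 6 atoms.
.oracle_isotopes <- list(
  C = c(0.9893, 0.0107),
  H = c(1 - 0.000115, 0.000115),
  N = c(1 - 0.00364, 0.00364),
  O = c(1 - 0.00038 - 0.00205, 0.00038, 0.00205),
  S = c(1 - 0.0075 - 0.0425, 0.0075, 0.0425)
)

oracle_isotope_pattern <- function(counts, max_k) {
  atoms <- rep(names(counts), counts)
  choices <- lapply(atoms, function(el) seq_along(.oracle_isotopes[[el]]) - 1L)
  grid <- do.call(expand.grid, c(choices, KEEP.OUT.ATTRS = FALSE))
  ab <- numeric(max_k + 1L)
  for (r in seq_len(max(nrow(grid), 1L))) {
    if (length(atoms)) {
      ks <- as.integer(grid[r, ])
      p <- prod(vapply(seq_along(atoms), function(i) {
        .oracle_isotopes[[atoms[i]]][ks[i] + 1L]
      }, numeric(1)))
      k <- sum(ks)
    } else {
      p <- 1; k <- 0L
    }
    if (k <= max_k) ab[k + 1L] <- ab[k + 1L] + p
  }
  ab / sum(ab)
}

# quick Dirichlet-style random simplex
random_simplex <- function(names) {
  g <- stats::rgamma(length(names), shape = 2)
  stats::setNames(g / sum(g), names)
}

random_truth <- function() {
  fr <- stats::runif(4, 0, 0.1)
  names(fr) <- c("Frag1", "Frag2", "Frag3", "Frag4")
  ground_truth(
    thiol = random_simplex(c("2xSH", "1xSH1xCys", "2xCys", "iDSB")),
    glyco = random_simplex(c("Man5", "G0", "G1F-GN", "G0F", "G1F",
                             "G1F-GN+NAc", "G2F", "G1FS", "G2FB", "G2FS",
                             "G2FS2")),
    reduction = c(heavy_light = stats::runif(1, 0, 0.3),
                  heavy_heavy = stats::runif(1, 0, 0.3)),
    fragmentation = fr,
    abundance = stats::runif(1, 0.5, 5)
  )
}
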