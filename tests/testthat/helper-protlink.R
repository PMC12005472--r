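# Shared test helpers.

# A random mixed acid/base system of n sites with symmetric non-negative
# (repulsive) couplings, for MC-vs-enumeration property tests.
randomSiteParams <- function(n, seed) {
  set.seed(seed)
  pka <- runif(n, 3, 10)
  acid <- runif(n) < 0.5
  W <- matrix(0, n, n)
  W[upper.tri(W)] <- runif(n * (n - 1) / 2, 0, 12)
  W <- W + t(W)
  list(pka = pka, acid = acid, W = W)
}

# Minimal PDB fixture with an altloc pair (B has the higher occupancy).
writeAltlocFixture <- function(path) {
  writeLines(c(
    "ATOM      1  N   ALA A   1      11.104   6.134  -6.504  1.00 10.00           N",
    "ATOM      2  CA AALA A   1      11.639   6.071  -5.147  0.40 10.00           C",
    "ATOM      3  CA BALA A   1      11.700   6.100  -5.200  0.60 10.00           C",
    "ATOM      4  C   ALA A   1      12.600   7.200  -4.800  1.00 10.00           C",
    "ATOM      5  N   GLY A   2      13.000   8.000  -5.700  1.00 10.00           N",
    "ATOM      6  CA  GLY A   2      14.000   9.000  -5.500  1.00 10.00           C",
    "END"), path)
  path
}

# Ionization enthalpies of the four buffers used throughout the tests
# (phosphate, ADA, HEPES, TRIS), kJ/mol.
bufferDH <- c(3.60, 12.23, 20.04, 47.45)
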