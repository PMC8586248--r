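# Physical and chemical constants used throughout the package.

#' @keywords internal
AVOGADRO <- 6.02214076e23

# In-chain (residue) elemental composition of the 20 canonical amino acids,
# i.e. the free amino acid minus one water. Columns C, H, N, O, S.
AA_FORMULA <- local({
  m <- rbind(
    A = c(3, 5, 1, 1, 0),
    R = c(6, 12, 4, 1, 0),
    N = c(4, 6, 2, 2, 0),
    D = c(4, 5, 1, 3, 0),
    C = c(3, 5, 1, 1, 1),
    E = c(5, 7, 1, 3, 0),
    Q = c(5, 8, 2, 2, 0),
    G = c(2, 3, 1, 1, 0),
    H = c(6, 7, 3, 1, 0),
    I = c(6, 11, 1, 1, 0),
    L = c(6, 11, 1, 1, 0),
    K = c(6, 12, 2, 1, 0),
    M = c(5, 9, 1, 1, 1),
    F = c(9, 9, 1, 1, 0),
    P = c(5, 7, 1, 1, 0),
    S = c(3, 5, 1, 2, 0),
    T = c(4, 7, 1, 2, 0),
    W = c(11, 10, 2, 1, 0),
    Y = c(9, 9, 1, 2, 0),
    V = c(5, 9, 1, 1, 0)
  )
  colnames(m) <- c("C", "H", "N", "O", "S")
  m
})

CANONICAL_AA <- rownames(AA_FORMULA)

# Monoisotopic and average atomic masses (IUPAC 2013 atomic weights;
# monoisotopic masses of the principal isotope from the AME2012 evaluation).
ELEMENT_MASS <- list(
  monoisotopic = c(C = 12, H = 1.0078250319, N = 14.0030740052,
                   O = 15.9949146221, S = 31.97207069),
  average = c(C = 12.0107, H = 1.00794, N = 14.0067, O = 15.9994, S = 32.065)
)

# Natural isotopic abundances (IUPAC 2013 representative values), expressed
# as probabilities by integer mass offset (+0, +1, +2, ... Da) from the
# lightest isotope. S has no +3 isotope, hence the explicit zero.
NATURAL_ABUNDANCE <- list(
  C = c(0.9893, 0.0107),
  H = c(0.999885, 0.000115),
  N = c(0.99636, 0.00364),
  O = c(0.99757, 0.00038, 0.00205),
  S = c(0.9499, 0.0075, 0.0425, 0, 0.0001)
)

#' Natural abundance of carbon-13
#'
#' Fraction of carbon atoms that are 13C at natural abundance (IUPAC 2013).
#' Passing this value as the enrichment to [isotope_pattern()] reproduces
#' the natural (unlabeled) isotopologue distribution.
#'
#' @export
natural_13c <- function() NATURAL_ABUNDANCE$C[2]

# Molar masses (g/mol) of the bioconversion species, standard chemistry.
SPECIES_MOLAR_MASS <- c(
  limonene = 136.23,
  carveol = 152.23,
  carvone = 150.22,
  dihydrocarveol = 154.25,
  dihydrocarvone = 152.23
)

#' Molar masses of the pathway species
#'
#' Named vector of molar masses (g/mol) for (-)-limonene,
#' (-)-trans-carveol, (-)-carvone, dihydrocarveol and dihydrocarvone.
#'
#' @export
species_molar_mass <- function() SPECIES_MOLAR_MASS
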