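#' Elemental composition of a peptide
#'
#' Sums the in-chain residue formulas and adds one water. The empty string
#' yields the composition of water.
#'
#' @param peptide Amino-acid string.
#' @return Named integer vector with counts of C, H, N, O, S, of class
#'   `elemental_composition`.
#' @export
elemental_composition <- function(peptide) {
  counts <- c(C = 0, H = 2, N = 0, O = 1, S = 0)  # one water
  if (nzchar(peptide)) {
    validate_sequence(peptide)
    chars <- strsplit(peptide, "")[[1]]
    counts <- counts + colSums(AA_FORMULA[chars, , drop = FALSE])
  }
  structure(as.integer(counts), names = names(counts),
            class = "elemental_composition")
}

# distribution of mass offsets for n atoms of one element, each drawn from
# `atom` (probabilities by +k Da offset), by repeated convolution
element_offset_distribution <- function(atom, n) {
  dist <- 1
  pow <- atom
  while (n > 0) {
    if (n %% 2 == 1) dist <- convolve_dist(dist, pow)
    n <- n %/% 2
    if (n > 0) pow <- convolve_dist(pow, pow)
  }
  dist
}

convolve_dist <- function(a, b) {
  out <- numeric(length(a) + length(b) - 1L)
  for (i in seq_along(a)) {
    if (a[i] > 0) out[i + seq_along(b) - 1L] <- out[i + seq_along(b) - 1L] + a[i] * b
  }
  out
}

#' Isotopologue distribution of a composition at a given 13C enrichment
#'
#' Computes the probability of each +k Da isotopologue by convolving
#' per-element isotope distributions at unit (1 Da) resolution. Carbon is
#' modeled as i.i.d. Bernoulli with 13C probability `p` per atom; H, N, O
#' and S stay at natural abundance. The distribution is truncated once the
#' cumulative abundance exceeds `1 - 1e-6` and renormalized.
#'
#' @param comp An [elemental_composition()] (or named vector with C, H, N,
#'   O, S counts).
#' @param p 13C enrichment, a fraction in \[0, 1\]. Defaults to natural
#'   abundance.
#' @return An object of class `isotope_pattern`: list with `abundances`
#'   (numeric vector indexed from +0 Da), `base_mass` (monoisotopic mass of
#'   the all-12C species in Da) and `enrichment`.
#' @export
isotope_pattern <- function(comp, p = natural_13c()) {
  stopifnot(p >= 0, p <= 1)
  counts <- as.integer(comp)
  names(counts) <- names(comp)
  dist <- 1
  for (el in names(counts)) {
    n <- counts[[el]]
    if (n == 0L) next
    atom <- if (el == "C") c(1 - p, p) else NATURAL_ABUNDANCE[[el]]
    dist <- convolve_dist(dist, element_offset_distribution(atom, n))
  }
  cum <- cumsum(dist)
  keep <- seq_len(min(which(cum > 1 - 1e-6), length(dist)))
  ab <- dist[keep] / sum(dist[keep])
  base <- sum(as.numeric(counts) * ELEMENT_MASS$monoisotopic[names(counts)])
  structure(list(abundances = ab, base_mass = base, enrichment = p),
            class = "isotope_pattern")
}

#' @export
print.isotope_pattern <- function(x, ...) {
  cat("<isotope_pattern> base mass", round(x$base_mass, 4), "Da, enrichment",
      x$enrichment, "\n")
  top <- order(x$abundances, decreasing = TRUE)[1:min(5, length(x$abundances))]
  for (i in sort(top)) {
    cat(sprintf("  +%d Da  %.4f\n", i - 1L, x$abundances[i]))
  }
  invisible(x)
}

#' Labeling-deficit fraction of a 13C-labeled standard
#'
#' Probability that a molecule of the labeled standard is *not* fully
#' 13C-labeled, `1 - p^nC`, where `nC` is the carbon count. With a labeled
#' standard quantified on its fully-labeled (monoisotopic heavy) peak only,
#' this is the fraction of standard signal lost to lighter deficit
#' isotopologues.
#'
#' @inheritParams isotope_pattern
#' @return Fraction in \[0, 1\].
#' @export
labeling_deficit_fraction <- function(comp, p) {
  stopifnot(p >= 0, p <= 1)
  nc <- as.integer(comp)[match("C", names(comp))]
  1 - p^nc
}
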