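#' Assemble a concatamer (QconCAT) standard protein
#'
#' Concatenates quantification peptides, in order, into a single artificial
#' standard protein, optionally between a leader tag (e.g. a His-tag
#' cassette) and a trailer tag. Every peptide-peptide boundary is recorded
#' as a junction for subsequent auditing.
#'
#' @param peptides Character vector of amino-acid peptides, in the order
#'   they appear in the standard.
#' @param name Name of the design.
#' @param leader_tag,trailer_tag Amino-acid strings prepended/appended to
#'   the peptide block (may be empty).
#' @return An object of class `concatamer`: a list with elements `name`,
#'   `peptides`, `leader_tag`, `trailer_tag`, `full_sequence` and
#'   `junctions` (tibble with `index`, `left`, `right`, `residues`).
#' @export
build_concatamer <- function(peptides, name = "qconcat",
                             leader_tag = "", trailer_tag = "") {
  if (length(peptides) < 1L) stop("at least one peptide is required")
  for (p in peptides) validate_sequence(p, p)
  if (nzchar(leader_tag)) validate_sequence(leader_tag, "leader_tag")
  if (nzchar(trailer_tag)) validate_sequence(trailer_tag, "trailer_tag")

  blocks <- c(if (nzchar(leader_tag)) leader_tag, peptides,
              if (nzchar(trailer_tag)) trailer_tag)
  full <- paste(blocks, collapse = "")
  nb <- length(blocks)
  junctions <- tibble::tibble(
    index = seq_len(nb - 1L),
    left = blocks[-nb],
    right = blocks[-1L],
    residues = paste0(substr(blocks[-nb], nchar(blocks[-nb]),
                             nchar(blocks[-nb])),
                      substr(blocks[-1L], 1L, 1L))
  )
  structure(list(name = name, peptides = peptides, leader_tag = leader_tag,
                 trailer_tag = trailer_tag, full_sequence = full,
                 junctions = junctions),
            class = "concatamer")
}

#' @export
print.concatamer <- function(x, ...) {
  cat("<concatamer>", x$name, "\n")
  cat("  peptides:", length(x$peptides), " junctions:", nrow(x$junctions), "\n")
  cat("  length:", nchar(x$full_sequence), "residues, average mass",
      round(protein_mass(x$full_sequence, "average") / 1000, 2), "kDa\n")
  invisible(x)
}

#' Audit concatamer junctions for peptide-release problems
#'
#' Digests the full concatamer sequence and inspects every junction for
#' conditions that prevent or bias quantitative release of the designed
#' peptides: a blocked junction (K/R followed by P, which trypsin cannot
#' cleave), a slow-cleaving acidic junction (K/R followed by D or E), and
#' junction-spanning missed-cleavage products that collide with a
#' quantification peptide. For an acidic junction the left-hand designed
#' peptide is recommended for exclusion from quantification, since part of
#' its signal persists as the spanning miscleavage product.
#'
#' @param design A [build_concatamer()] object.
#' @param max_missed Missed cleavages used in the audit digest.
#' @return A tibble with one row per junction: `index`, `left`, `right`,
#'   `residues`, `cleavable`, `risk_flags` (comma-separated), the
#'   junction-`spanning_peptide` observed in the digest (`NA` if none) and
#'   `exclude_peptide` (`NA` if no exclusion is recommended).
#' @export
audit_junctions <- function(design, max_missed = 1) {
  stopifnot(inherits(design, "concatamer"))
  products <- digest(list(id = design$name, sequence = design$full_sequence),
                     max_missed = max_missed)
  released <- products$peptide[products$missed_cleavages == 0L]

  res <- design$junctions
  audits <- lapply(seq_len(nrow(res)), function(i) {
    left <- res$left[i]; right <- res$right[i]
    jr <- res$residues[i]
    left_res <- substr(jr, 1, 1); right_res <- substr(jr, 2, 2)
    flags <- character(0)
    cleavable <- left_res %in% c("K", "R") && right_res != "P"
    if (left_res %in% c("K", "R") && right_res == "P") flags <- c(flags, "KP/RP blocked")
    if (!left_res %in% c("K", "R")) flags <- c(flags, "no tryptic site")
    if (cleavable && right_res %in% c("D", "E")) flags <- c(flags, "acidic neighbor")
    spanning <- NA_character_
    exclude <- NA_character_
    span <- paste0(left, right)
    if (span %in% products$peptide[products$missed_cleavages > 0L]) {
      spanning <- span
      if (!cleavable || right_res %in% c("D", "E")) {
        flags <- c(flags, "spanning product collides with quantification peptide")
        exclude <- left
      }
    }
    if (!cleavable) exclude <- left
    tibble::tibble(
      cleavable = cleavable,
      risk_flags = paste(flags, collapse = ", "),
      spanning_peptide = spanning,
      exclude_peptide = exclude,
      left_released = left %in% released,
      right_released = right %in% released
    )
  })
  cbind(res, do.call(rbind, audits))
}

#' Mass of a protein or peptide
#'
#' Sum of residue masses plus one water, from the elemental composition.
#'
#' @param sequence Amino-acid string (may be empty, giving the mass of
#'   water).
#' @param kind `"monoisotopic"` or `"average"`.
#' @return Mass in Da.
#' @export
protein_mass <- function(sequence, kind = c("monoisotopic", "average")) {
  kind <- match.arg(kind)
  comp <- elemental_composition(sequence)
  sum(comp * ELEMENT_MASS[[kind]][names(comp)])
}
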