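#' Read protein sequences from a FASTA file
#'
#' Reads one record per FASTA entry. The record id is the first
#' whitespace-delimited token of the header; a `role=` tag in the header
#' (e.g. `>cyp71d18 role=P450`) assigns the pathway role, otherwise the
#' role is `"other"`. Sequences are uppercased and trailing `*` stop
#' symbols are stripped.
#'
#' @param path Path to a FASTA file of amino-acid sequences.
#' @return A tibble with columns `id`, `sequence`, `role`.
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("FASTA file not found: ", path)
  # read without alphabet filtering so that non-canonical residues are
  # caught by validation instead of being silently dropped
  set <- tryCatch(
    Biostrings::readBStringSet(path),
    error = function(e) stop("malformed FASTA in ", path, ": ", conditionMessage(e))
  )
  if (length(set) == 0L) stop("no sequences in FASTA file: ", path)
  headers <- names(set)
  ids <- vapply(strsplit(headers, "\\s+"), `[[`, character(1), 1L)
  if (anyDuplicated(ids)) {
    dup <- unique(ids[duplicated(ids)])
    stop("duplicate FASTA id(s): ", paste(dup, collapse = ", "))
  }
  roles <- vapply(headers, function(h) {
    m <- regmatches(h, regexpr("role=\\S+", h))
    if (length(m) == 0L) "other" else sub("^role=", "", m)
  }, character(1), USE.NAMES = FALSE)
  seqs <- toupper(gsub("\\*", "", as.character(set)))
  for (i in seq_along(seqs)) validate_sequence(seqs[i], ids[i])
  tibble::tibble(id = ids, sequence = unname(seqs), role = roles)
}

#' @keywords internal
validate_sequence <- function(sequence, id = "<sequence>") {
  if (!nzchar(sequence)) stop("empty sequence for ", id)
  bad <- setdiff(strsplit(sequence, "")[[1]], CANONICAL_AA)
  if (length(bad) > 0L) {
    stop("non-canonical residue(s) ", paste(unique(bad), collapse = ", "),
         " in ", id)
  }
  invisible(TRUE)
}

# Positions after which trypsin cleaves: after K or R unless followed by P.
cleavage_sites <- function(sequence) {
  chars <- strsplit(sequence, "")[[1]]
  n <- length(chars)
  if (n < 2L) return(integer(0))
  idx <- which(chars[-n] %in% c("K", "R"))
  idx[chars[idx + 1L] != "P"]
}

#' In-silico tryptic digestion
#'
#' Cleaves after K or R except when the next residue is P (the Keil rule),
#' and returns all peptides carrying up to `max_missed` internal missed
#' cleavage sites. Coordinates are 0-based half-open into the parent
#' sequence; the residue context on either side is reported, with `"-"`
#' marking a protein terminus.
#'
#' @param protein Either a single amino-acid string or a one-row tibble /
#'   list with fields `id` and `sequence` (as returned by [read_fasta()]).
#' @param max_missed Maximum number of missed cleavages (0 to 3).
#' @return A tibble with columns `peptide`, `parent_id`, `start`, `end`,
#'   `missed_cleavages`, `n_term_context`, `c_term_context`, ordered by
#'   (`start`, `missed_cleavages`).
#' @export
digest <- function(protein, max_missed = 1) {
  if (is.character(protein) && length(protein) == 1L) {
    protein <- list(id = "<sequence>", sequence = protein)
  }
  sequence <- protein$sequence
  id <- protein$id
  if (length(sequence) != 1L) stop("digest() expects a single protein")
  validate_sequence(sequence, id)
  stopifnot(max_missed >= 0, max_missed <= 3)

  chars <- strsplit(sequence, "")[[1]]
  n <- length(chars)
  # fragment boundaries: 0-based cut points including both termini
  cuts <- c(0L, cleavage_sites(sequence), n)
  nfrag <- length(cuts) - 1L
  out <- vector("list", nfrag * (max_missed + 1L))
  k <- 0L
  for (i in seq_len(nfrag)) {
    for (m in 0:max_missed) {
      j <- i + m
      if (j > nfrag) break
      start <- cuts[i]
      end <- cuts[j + 1L]
      k <- k + 1L
      out[[k]] <- list(
        peptide = substr(sequence, start + 1L, end),
        parent_id = id,
        start = start,
        end = end,
        missed_cleavages = m,
        n_term_context = if (start == 0L) "-" else chars[start],
        c_term_context = if (end == n) "-" else chars[end + 1L]
      )
    }
  }
  res <- do.call(rbind, lapply(out[seq_len(k)], function(x)
    tibble::as_tibble(x)))
  res[order(res$start, res$missed_cleavages), ]
}

#' Default proteotypic peptide selection rules
#'
#' Filters and scoring used by [select_qpeptides()]. Peptides must be fully
#' tryptic with no missed cleavage, within the length bounds, free of
#' chemically labile residues (M, C and the deamidation-prone NG motif),
#' not ragged (not preceded/followed by an additional K/R), and unique
#' across the whole protein set. The proxy detection-strength score favors
#' mid-length peptides and penalizes histidines and extreme hydropathy;
#' it stands in for the empirical LC-MS response used when spectra are
#' available.
#'
#' @param min_length,max_length Length bounds (residues).
#' @param forbid_residues Residues that disqualify a candidate.
#' @param forbid_motifs Character vector of disallowed subsequences.
#' @param top_k Number of peptides to select per protein.
#' @return A list of class `qpeptide_rules`.
#' @export
qpeptide_rules <- function(min_length = 6, max_length = 25,
                           forbid_residues = c("M", "C"),
                           forbid_motifs = "NG",
                           top_k = 2) {
  structure(list(min_length = min_length, max_length = max_length,
                 forbid_residues = forbid_residues,
                 forbid_motifs = forbid_motifs, top_k = top_k),
            class = "qpeptide_rules")
}

# Kyte-Doolittle hydropathy values
KD_HYDROPATHY <- c(A = 1.8, R = -4.5, N = -3.5, D = -3.5, C = 2.5, E = -3.5,
                   Q = -3.5, G = -0.4, H = -3.2, I = 4.5, L = 3.8, K = -3.9,
                   M = 1.9, F = 2.8, P = -1.6, S = -0.8, T = -0.7, W = -0.9,
                   Y = -1.3, V = 4.2)

qpeptide_score <- function(peptide) {
  n <- nchar(peptide)
  chars <- strsplit(peptide, "")[[1]]
  # mid-length (8-15) peptides fly and fragment well
  len_pen <- if (n < 8) (8 - n) * 0.5 else if (n > 15) (n - 15) * 0.25 else 0
  his_pen <- sum(chars == "H") * 0.5
  gravy <- mean(KD_HYDROPATHY[chars])
  hyd_pen <- max(0, abs(gravy) - 1.5)
  round(10 - len_pen - his_pen - hyd_pen, 4)
}

#' Select quantification peptides for a set of target proteins
#'
#' Digests each protein without missed cleavages, applies the selection
#' rules and ranks the surviving candidates by the proxy detection-strength
#' score. Failed candidates carry machine-readable rejection reasons. A
#' protein with no passing candidate yields a warning and an empty
#' selection rather than an error.
#'
#' @param proteins Tibble from [read_fasta()] (columns `id`, `sequence`).
#' @param rules A [qpeptide_rules()] configuration.
#' @return A tibble with columns `parent_id`, `peptide`, `start`, `end`,
#'   `passed`, `reasons` (comma-separated failures, `""` if passed),
#'   `score`, `rank` (within parent, passing candidates only) and
#'   `selected`.
#' @export
select_qpeptides <- function(proteins, rules = qpeptide_rules()) {
  stopifnot(inherits(rules, "qpeptide_rules"))
  digests <- lapply(seq_len(nrow(proteins)), function(i)
    digest(proteins[i, ], max_missed = 0))
  all_pep <- do.call(rbind, digests)
  # peptides seen in more than one protein are not proteotypic
  tab <- table(unique(all_pep[, c("peptide", "parent_id")])$peptide)
  shared <- names(tab)[tab > 1L]

  res <- lapply(digests, function(d) {
    reasons <- vapply(seq_len(nrow(d)), function(i) {
      p <- d$peptide[i]
      r <- character(0)
      n <- nchar(p)
      if (n < rules$min_length || n > rules$max_length) r <- c(r, "length")
      chars <- strsplit(p, "")[[1]]
      if (any(chars %in% rules$forbid_residues)) r <- c(r, "labile residue")
      if (any(vapply(rules$forbid_motifs, grepl, logical(1), x = p, fixed = TRUE)))
        r <- c(r, "labile motif")
      # a tryptic peptide is always preceded by K/R; "ragged" means an
      # adjacent additional K/R: next residue K/R, or the peptide itself
      # starting with K/R (preceding KK/RR or KP/RP run)
      if (chars[1] %in% c("K", "R") || d$c_term_context[i] %in% c("K", "R"))
        r <- c(r, "ragged end")
      if (p %in% shared) r <- c(r, "not unique")
      paste(r, collapse = ", ")
    }, character(1))
    d$passed <- reasons == ""
    d$reasons <- reasons
    d$score <- vapply(d$peptide, qpeptide_score, numeric(1), USE.NAMES = FALSE)
    d <- d[order(-d$passed, -d$score), ]
    d$rank <- NA_integer_
    d$rank[d$passed] <- seq_len(sum(d$passed))
    d$selected <- !is.na(d$rank) & d$rank <= rules$top_k
    if (!any(d$passed)) {
      warning("no quantification peptide candidates pass for protein ",
              d$parent_id[1])
    }
    d
  })
  out <- do.call(rbind, res)
  out[, c("parent_id", "peptide", "start", "end", "missed_cleavages",
          "passed", "reasons", "score", "rank", "selected")]
}
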