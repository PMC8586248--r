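# Independent oracles used by the property tests.

# brute-force tryptic digestion: enumerate all intervals between cleavage
# points and count internal sites directly
oracle_digest <- function(sequence, max_missed) {
  chars <- strsplit(sequence, "")[[1]]
  n <- length(chars)
  sites <- integer(0)
  for (i in seq_len(max(0, n - 1))) {
    if (chars[i] %in% c("K", "R") && chars[i + 1] != "P") sites <- c(sites, i)
  }
  cuts <- c(0L, sites, n)
  peps <- character(0)
  for (a in seq_along(cuts)) {
    for (b in seq_along(cuts)) {
      if (b <= a) next
      internal <- sum(sites > cuts[a] & sites < cuts[b])
      if (internal <= max_missed) {
        peps <- c(peps, paste0(
          sprintf("%d:%d:%d", cuts[a], cuts[b], internal)))
      }
    }
  }
  sort(peps)
}

digest_as_keys <- function(d) {
  sort(sprintf("%d:%d:%d", d$start, d$end, d$missed_cleavages))
}

random_protein <- function(n, seed) {
  aa <- c("A", "R", "N", "D", "C", "E", "Q", "G", "H", "I", "L", "K", "M",
          "F", "P", "S", "T", "W", "Y", "V")
  set.seed(seed)
  paste(sample(aa, n, replace = TRUE), collapse = "")
}

# exhaustive isotopologue enumeration for tiny compositions: one draw per
# atom over its isotope offsets
oracle_pattern <- function(counts, p13c) {
  natural <- list(
    C = c(1 - p13c, p13c),
    H = c(0.999885, 0.000115),
    N = c(0.99636, 0.00364),
    O = c(0.99757, 0.00038, 0.00205),
    S = c(0.9499, 0.0075, 0.0425, 0, 0.0001)
  )
  atoms <- list()
  for (el in names(counts)) {
    if (counts[[el]] > 0) {
      atoms <- c(atoms, rep(list(natural[[el]]), counts[[el]]))
    }
  }
  if (length(atoms) == 0) return(1)
  grid <- expand.grid(lapply(atoms, function(a) seq_along(a) - 1L))
  probs <- expand.grid(lapply(atoms, function(a) a))
  total_offset <- rowSums(grid)
  prob <- apply(probs, 1, prod)
  out <- numeric(max(total_offset) + 1L)
  for (i in seq_along(prob)) {
    out[total_offset[i] + 1L] <- out[total_offset[i] + 1L] + prob[i]
  }
  out
}
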