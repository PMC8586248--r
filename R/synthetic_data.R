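# Synthetic-data generator: fixture proteome, fixture concatamer standard,
# MRM peak tables with labeling deficit and noise, and bioconversion titer
# tables, all from named strain scenarios with known ground truth.
#
# All fixture sequences are synthetic: decoy segments around the published
# quantification peptides, scaled down from the real proteins.

# quantification peptides (two per quantified target) and the extra
# peptide from the alternative P450 candidate that follows the slow
# acidic junction in the standard
QPEPTIDES <- list(
  cyp71d18 = c("VLDPNFADR", "GLDLNSELATK"),
  atr2 = c("TLVELAGSDFK", "VVDDILVEQGAQR"),
  ispd = c("AVYGLDSNAVK", "SLTEDVLNHFR"),
  cyp102a1 = c("EDTVLGGEYPLEK")
)

# deterministic per-peptide MRM response factors (area units per pmol)
RESPONSE_FACTORS <- c(
  VLDPNFADR = 1.00e4, GLDLNSELATK = 1.35e4,
  TLVELAGSDFK = 0.80e4, VVDDILVEQGAQR = 0.90e4,
  AVYGLDSNAVK = 1.20e4, SLTEDVLNHFR = 1.10e4,
  EDTVLGGEYPLEK = 0.70e4
)

#' Map of quantification peptides to target proteins
#'
#' @return Tibble with columns `peptide`, `protein_id` and `role` for the
#'   six quantification peptides of the fixture design.
#' @export
qpeptide_map <- function() {
  tibble::tibble(
    peptide = unlist(QPEPTIDES[c("cyp71d18", "atr2", "ispd")],
                     use.names = FALSE),
    protein_id = rep(c("cyp71d18", "atr2", "ispd"), each = 2),
    role = rep(c("P450", "CPR", "CDH"), each = 2)
  )
}

#' Synthetic five-protein fixture proteome
#'
#' Deterministic synthetic stand-ins for the five target proteins (the
#' real sequences are not redistributed here): each embeds its published
#' or placeholder quantification peptides in clean tryptic context between
#' decoy segments.
#'
#' @param path Optional path; when given, the proteome is also written as
#'   FASTA with `role=` header tags.
#' @return Tibble with columns `id`, `sequence`, `role`.
#' @export
fixture_proteome <- function(path = NULL) {
  seqs <- c(
    cyp71d18 = paste0("MTDSLAQFLENPLK", "VLDPNFADR", "ESIAGQLYDSVTK",
                      "GLDLNSELATK", "ANDLESVQGTLW"),
    atr2 = paste0("MSSNTDLLVAQGK", "TLVELAGSDFK", "DVATQFESLNR",
                  "VVDDILVEQGAQR", "EGQVSTLADNLW"),
    ispd = paste0("MAEQTLDSFVNK", "AVYGLDSNAVK", "GDLVSETQALR",
                  "SLTEDVLNHFR", "ATDSLQEGVNFW"),
    cyp102a1 = paste0("MTIDEAQSLVTK", "EDTVLGGEYPLEK", "SGDFLATQVNER",
                      "TFDSLVAGNELK", "ALDVESQGTNLW"),
    limc = paste0("MSTAVDQELGNK", "FNTDVAGELSR", "EQLDSVTAGNFK",
                  "YLDAVSTEGNQK", "AVSELDQTGNLW")
  )
  roles <- c(cyp71d18 = "P450", atr2 = "CPR", ispd = "CDH",
             cyp102a1 = "P450", limc = "CDH")
  out <- tibble::tibble(id = names(seqs), sequence = unname(seqs),
                        role = unname(roles[names(seqs)]))
  if (!is.null(path)) {
    lines <- unlist(lapply(seq_len(nrow(out)), function(i)
      c(sprintf(">%s role=%s synthetic", out$id[i], out$role[i]),
        out$sequence[i])))
    writeLines(lines, path)
  }
  out
}

#' Synthetic fixture concatamer standard
#'
#' Concatenates the quantification peptides (the published miscleavage
#' pair adjacent, reproducing the slow R|E junction) behind a His-tag
#' leader, padded with a glycine/serine-rich tryptic spacer so the implied
#' molar mass of the standard matches the 2 ug = 100.9 pmol spike
#' (~19.82 kDa average mass).
#'
#' @return A [build_concatamer()] object named `"qconcat_fixture"`.
#' @export
fixture_concatamer <- function() {
  peps <- c("VLDPNFADR", "GLDLNSELATK", "TLVELAGSDFK", "AVYGLDSNAVK",
            "VVDDILVEQGAQR", "EDTVLGGEYPLEK", "SLTEDVLNHFR")
  leader <- "MGSSHHHHHHSSGLVPR"
  filler <- "GSSTAGK"
  core_mass <- protein_mass(paste0(leader, paste(peps, collapse = "")),
                            "average")
  water <- protein_mass("", "average")
  per_filler <- protein_mass(filler, "average") - water
  n <- max(0L, round((19820 - core_mass) / per_filler))
  build_concatamer(peps, name = "qconcat_fixture", leader_tag = leader,
                   trailer_tag = strrep(filler, n))
}

#' Measurement-noise model for synthetic MRM tables
#'
#' @param cv Multiplicative coefficient of variation of peak areas
#'   (lognormal, mean 1). 0 disables noise.
#' @param background_frac Additive light-channel background, as a fraction
#'   of the median heavy area of the sample. 0 disables background.
#' @param enrichment 13C enrichment of the labeled standard.
#' @param digestion_completeness Named per-peptide release factors applied
#'   to the standard (heavy) signal; the peptide upstream of the slow
#'   acidic junction is released incompletely by default.
#' @param seed Integer seed; the same seed yields identical tables.
#' @return A list of class `noise_model`.
#' @export
noise_model <- function(cv = 0.05, background_frac = 0.005,
                        enrichment = 0.99,
                        digestion_completeness = c(VVDDILVEQGAQR = 0.7),
                        seed = 1L) {
  stopifnot(cv >= 0, background_frac >= 0,
            enrichment >= 0, enrichment <= 1)
  structure(list(cv = cv, background_frac = background_frac,
                 enrichment = enrichment,
                 digestion_completeness = digestion_completeness,
                 seed = as.integer(seed)),
            class = "noise_model")
}

#' Noise-free measurement model
#'
#' Convenience wrapper: no area noise, no background, complete digestion,
#' 99% enrichment.
#'
#' @param enrichment 13C enrichment of the labeled standard.
#' @return A [noise_model()].
#' @export
noise_free_model <- function(enrichment = 0.99) {
  noise_model(cv = 0, background_frac = 0, enrichment = enrichment,
              digestion_completeness = c(VVDDILVEQGAQR = 1), seed = 1L)
}

# run code with a fixed RNG seed without disturbing the caller's RNG
with_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv())) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()))
  }
  set.seed(seed)
  code
}

#' Named strain scenarios with ground truth
#'
#' Returns the documented default ground truth for one of the study
#' scenarios: the single-enzyme assay strains (`Mpa`, `Hc`), the
#' single-strain pathway variants (`MpaHc`, `MpaLc`), the OD-based
#' two-strain mixtures (`mix_100_100`, `mix_100_10`, `mix_100_1`) and the
#' `negative_control`. Per-cell copy numbers are synthetic design choices;
#' the P450/CDH ratio of every scenario equals its reported value (0.004,
#' 12, 0.388, 3.4, 16), with mixture ratios encoded independently per
#' scenario because the reported mixture ratios are not mutually
#' consistent under proportional OD mixing.
#'
#' @param name Scenario name.
#' @return A list of class `strain_scenario`: `name`, `profile` (pooled
#'   [enzyme_profile()] seen by the quantification pipeline), `conditions`
#'   ([reaction_conditions()] of the scenario's reaction),
#'   `activity_product` (species measured in the activity assay, or `NA`),
#'   `ratio_truth` (P450/CDH), and for mixtures `components` (profiles)
#'   and `od` (mixing proportions).
#' @export
make_scenario <- function(name) {
  valid <- c("Mpa", "Hc", "MpaHc", "MpaLc", "mix_100_100", "mix_100_10",
             "mix_100_1", "negative_control")
  if (!name %in% valid) {
    stop("unknown scenario '", name, "'; valid: ", paste(valid, collapse = ", "))
  }
  bioconv <- reaction_conditions(od600 = 20, duration_h = 16,
                                 substrate = "limonene",
                                 substrate_mg_per_l = 100)
  assay <- function(substrate) {
    reaction_conditions(od600 = 5, duration_h = 2, substrate = substrate,
                        substrate_mg_per_l = 100)
  }
  mixture <- function(nm, ratio, od_a, od_b) {
    a <- enzyme_profile(p450 = 8000, cpr = 16000, cdh = 0, strain = "Mpa_batch")
    b <- enzyme_profile(cdh = 8000 * od_a / (ratio * od_b),
                        strain = "Hc_batch")
    list(name = nm, profile = pool_profiles(a, b, od_a, od_b, strain = nm),
         components = list(a = a, b = b), od = c(a = od_a, b = od_b),
         conditions = bioconv, activity_product = NA_character_,
         ratio_truth = ratio)
  }
  sc <- switch(name,
    Mpa = list(name = name,
               profile = enzyme_profile(p450 = 33400, cpr = 66800, cdh = 0,
                                        strain = "Mpa"),
               conditions = assay("limonene"), activity_product = "carveol",
               ratio_truth = Inf),
    Hc = list(name = name,
              profile = enzyme_profile(cdh = 10000, strain = "Hc"),
              conditions = assay("carveol"), activity_product = "carvone",
              ratio_truth = 0),
    MpaHc = list(name = name,
                 profile = enzyme_profile(p450 = 269, cpr = 40000,
                                          cdh = 67250, strain = "MpaHc"),
                 conditions = bioconv, activity_product = NA_character_,
                 ratio_truth = 0.004),
    MpaLc = list(name = name,
                 profile = enzyme_profile(p450 = 20000, cpr = 40000,
                                          cdh = 20000 / 12, strain = "MpaLc"),
                 conditions = bioconv, activity_product = NA_character_,
                 ratio_truth = 12),
    mix_100_100 = mixture(name, 0.388, 100, 100),
    mix_100_10 = mixture(name, 3.4, 100, 10),
    mix_100_1 = mixture(name, 16, 100, 1),
    negative_control = list(name = name,
                            profile = enzyme_profile(strain = "BL21"),
                            conditions = bioconv,
                            activity_product = NA_character_,
                            ratio_truth = NA_real_)
  )
  structure(sc, class = "strain_scenario")
}

scenario_true_pmol <- function(scenario, cells) {
  copies <- c(cyp71d18 = scenario$profile$p450,
              atr2 = scenario$profile$cpr,
              ispd = scenario$profile$cdh)
  copies * cells / AVOGADRO * 1e12
}

#' Synthetic MRM peak table for a scenario
#'
#' Emulates the targeted-proteomics data flow: the heavy (standard)
#' channel carries the spiked amount attenuated to its fully-labeled
#' `p^nC` fraction and by any incomplete junction release; the light
#' (analyte) channel carries the scenario's true per-cell abundances plus
#' an additive background; multiplicative lognormal noise at the stated CV
#' is applied to both channels. A matching negative-control table
#' (background only in the light channel) and a ground-truth sidecar are
#' returned alongside.
#'
#' @param scenario A [make_scenario()] object.
#' @param noise A [noise_model()].
#' @param replicates Number of replicate samples (independent clones).
#' @param spiked_pmol Standard spike per digest (pmol).
#' @param cells Cells represented per digest.
#' @return List with elements `peaks`, `meta`, `control` (peak table of
#'   the negative control) and `truth` (tibble `protein_id`,
#'   `copies_per_cell`).
#' @export
synth_peak_table <- function(scenario, noise = noise_model(),
                             replicates = 3, spiked_pmol = 100.9,
                             cells = 2.5e8) {
  stopifnot(inherits(scenario, "strain_scenario"),
            inherits(noise, "noise_model"))
  map <- qpeptide_map()
  peptides <- c(map$peptide, "EDTVLGGEYPLEK")
  nc <- vapply(peptides, function(p)
    as.integer(elemental_composition(p))[1], integer(1))
  labeled_frac <- noise$enrichment^nc
  release <- stats::setNames(rep(1, length(peptides)), peptides)
  dc <- noise$digestion_completeness
  release[names(dc)[names(dc) %in% peptides]] <- dc[names(dc) %in% peptides]

  true_pmol <- scenario_true_pmol(scenario, cells)
  pep_true <- stats::setNames(
    true_pmol[c(rep(c("cyp71d18", "atr2", "ispd"), each = 2), NA)],
    peptides)
  pep_true["EDTVLGGEYPLEK"] <- 0  # CYP102A1 not expressed in any strain

  heavy0 <- RESPONSE_FACTORS[peptides] * spiked_pmol * labeled_frac *
    release[peptides]
  bg <- noise$background_frac * stats::median(heavy0)

  jitter <- function(x, n) {
    if (noise$cv == 0) return(x)
    s <- sqrt(log(1 + noise$cv^2))
    x * stats::rlnorm(n, meanlog = -s^2 / 2, sdlog = s)
  }
  with_seed(noise$seed, {
    rows <- lapply(seq_len(replicates), function(r) {
      sid <- sprintf("%s_rep%d", scenario$name, r)
      light0 <- RESPONSE_FACTORS[peptides] * pep_true[peptides] + bg
      tibble::tibble(
        sample_id = sid,
        peptide = rep(peptides, 2),
        channel = rep(c("light", "heavy"), each = length(peptides)),
        area = c(jitter(unname(light0), length(peptides)),
                 jitter(unname(heavy0), length(peptides)))
      )
    })
    peaks <- do.call(rbind, rows)
    control <- tibble::tibble(
      sample_id = "negative_control",
      peptide = rep(peptides, 2),
      channel = rep(c("light", "heavy"), each = length(peptides)),
      area = c(jitter(rep(bg, length(peptides)), length(peptides)),
               jitter(unname(heavy0), length(peptides)))
    )
    meta <- tibble::tibble(
      sample_id = c(sprintf("%s_rep%d", scenario$name, seq_len(replicates)),
                    "negative_control"),
      spiked_pmol = spiked_pmol,
      total_protein_ug = 50,
      cells_in_digest = cells,
      is_negative_control = c(rep(FALSE, replicates), TRUE)
    )
    truth <- tibble::tibble(
      protein_id = names(true_pmol),
      copies_per_cell = c(scenario$profile$p450, scenario$profile$cpr,
                          scenario$profile$cdh)
    )
    list(peaks = peaks, meta = meta, control = control, truth = truth)
  })
}

#' Synthetic bioconversion titer table for a scenario
#'
#' Simulates the scenario's reaction with the shipped calibrated
#' coefficients and emits per-replicate endpoint concentrations with
#' multiplicative lognormal noise.
#'
#' @inheritParams synth_peak_table
#' @param params Kinetic coefficients for the simulation.
#' @return Tibble with columns `scenario`, `replicate`, `species`,
#'   `concentration_mg_per_L`, `time_h`.
#' @export
synth_titer_table <- function(scenario, noise = noise_model(),
                              replicates = 3,
                              params = default_kinetic_params()) {
  stopifnot(inherits(scenario, "strain_scenario"))
  tc <- simulate_bioconversion(scenario$profile, scenario$conditions, params)
  fin <- tc[nrow(tc), ]
  species <- names(SPECIES_MOLAR_MASS)
  endpoint <- vapply(species, function(sp) fin[[sp]], numeric(1))
  nm <- scenario$name
  dur <- scenario$conditions$duration_h
  with_seed(noise$seed, {
    rows <- lapply(seq_len(replicates), function(r) {
      conc <- if (noise$cv == 0) endpoint else {
        s <- sqrt(log(1 + noise$cv^2))
        endpoint * stats::rlnorm(length(endpoint), -s^2 / 2, s)
      }
      tibble::tibble(scenario = nm, replicate = r, species = species,
                     concentration_mg_per_L = unname(conc),
                     time_h = dur)
    })
    do.call(rbind, rows)
  })
}

#' Write a peak table, sample metadata or titer table to CSV
#'
#' @param x Tibble to write.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_table_csv <- function(x, path) {
  readr::write_csv(x, path, progress = FALSE)
  invisible(path)
}

#' Recover the P450/CDH ratio of a scenario through the full pipeline
#'
#' Generates a synthetic peak table for the scenario, quantifies it with
#' negative-control subtraction, labeling-deficit correction and the
#' standard peptide exclusion (the miscleavage-biased CPR peptide), and
#' returns the recovered P450/CDH copies-per-cell ratio.
#'
#' @inheritParams synth_peak_table
#' @return List with `ratio`, `abundances` (tibble from
#'   [quantify_samples()]) and `truth_ratio`.
#' @export
recover_ratio <- function(scenario, noise = noise_free_model(),
                          replicates = 1) {
  syn <- synth_peak_table(scenario, noise, replicates)
  ab <- quantify_samples(
    syn$peaks, syn$meta, qpeptide_map(), control = syn$control,
    enrichment = noise$enrichment, deficit_correction = TRUE,
    exclusions = c(VVDDILVEQGAQR = "junction miscleavage"))
  p450 <- ab$copies_per_cell[ab$protein_id == "cyp71d18"]
  cdh <- ab$copies_per_cell[ab$protein_id == "ispd"]
  list(ratio = if (cdh == 0) Inf else p450 / cdh, abundances = ab,
       truth_ratio = scenario$ratio_truth)
}
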