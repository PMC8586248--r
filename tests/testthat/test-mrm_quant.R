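test_that("peak tables and sample metadata round-trip through CSV/JSON", {
  syn <- synth_peak_table(make_scenario("MpaLc"), noise_model(seed = 5), 2)
  f <- withr::local_tempfile(fileext = ".csv")
  write_table_csv(syn$peaks, f)
  expect_silent(back <- read_peak_table(f))
  for (col in names(syn$peaks)) {
    expect_equal(back[[col]], syn$peaks[[col]], info = col)
  }

  fm <- withr::local_tempfile(fileext = ".csv")
  write_table_csv(syn$meta, fm)
  backm <- read_sample_meta(fm)
  fj <- withr::local_tempfile(fileext = ".json")
  jsonlite::write_json(syn$meta, fj, auto_unbox = FALSE, digits = NA)
  backj <- read_sample_meta(fj)
  for (col in names(syn$meta)) {
    expect_equal(backm[[col]], syn$meta[[col]], info = col)
    expect_equal(backj[[col]], syn$meta[[col]], info = col)
  }
})

test_that("peak table validation rejects malformed input", {
  ok <- tibble::tibble(sample_id = "s", peptide = "PEPK",
                       channel = c("light", "heavy"), area = c(1, 2))
  expect_silent(validate_peak_table(ok))
  expect_error(validate_peak_table(ok[, -4]), "missing column.*area")
  expect_error(validate_peak_table(rbind(ok, ok[1, ])), "duplicated")
  bad <- ok; bad$area[1] <- -1
  expect_error(validate_peak_table(bad), "negative")
  bad <- ok; bad$channel[1] <- "medium"
  expect_error(validate_peak_table(bad), "light.*heavy")
})

test_that("negative-control subtraction clamps at zero and spares heavy", {
  samples <- tibble::tibble(
    sample_id = "s1", peptide = rep(c("AAK", "GGR"), each = 2),
    channel = rep(c("light", "heavy"), 2), area = c(100, 500, 30, 400))
  ctl0 <- tibble::tibble(sample_id = "nc", peptide = c("AAK", "GGR"),
                         channel = "light", area = c(0, 0))
  expect_equal(subtract_negative_control(samples, ctl0)$area,
               samples$area)
  ctl <- tibble::tibble(sample_id = "nc", peptide = c("AAK", "GGR"),
                        channel = "light", area = c(40, 50))
  out <- subtract_negative_control(samples, ctl)
  expect_equal(out$area, c(60, 500, 0, 400))
  expect_warning(
    subtract_negative_control(samples, ctl[ctl$peptide == "AAK", ]),
    "GGR")
})

test_that("peptide quantification inverts the labeled-standard model", {
  expect_equal(quantify_peptide(5e4, 5e4), 100.9)
  expect_equal(quantify_peptide(0, 5e4), 0)
  expect_warning(res <- quantify_peptide(10, 0), "heavy")
  expect_true(is.na(res))

  # heavy area carries only the fully-labeled p^nC fraction of the spike
  spike <- 100.9; p <- 0.99; nc <- 46; gain <- 1.7e4; truth <- 8.3
  heavy <- gain * spike * p^nc
  light <- gain * truth
  expect_equal(quantify_peptide(light, heavy, spike,
                                deficit_correction = p^nc), truth)
})

test_that("copies per cell is the Avogadro-scaled quotient", {
  expect_equal(copies_per_cell(1, 6.02214076e11), 1)
  expect_equal(copies_per_cell(0.1, 6.02214076e8), 100)
  expect_equal(copies_per_cell(0, 1e8), 0)
  expect_error(copies_per_cell(1, 0), "positive")
})

test_that("protein abundance averages the non-excluded peptides", {
  pa <- protein_abundance("cyp71d18", c(PEP1 = 900, PEP2 = 1100))
  expect_equal(pa$copies_per_cell, 1000)
  pa <- protein_abundance("atr2", c(A = 800, B = 5000),
                          exclusions = c(B = "junction miscleavage"))
  expect_equal(pa$copies_per_cell, 800)
  expect_equal(pa$peptides_excluded, c(B = "junction miscleavage"))
  pa <- protein_abundance("x", c(A = 7, B = 7))
  expect_equal(pa$copies_per_cell, 7)
  expect_warning(pa <- protein_abundance("x", c(A = 1),
                                         exclusions = c(A = "r")),
                 "undefined")
  expect_true(is.na(pa$copies_per_cell))
})

test_that("noise-free synthetic tables are recovered exactly", {
  for (nm in c("MpaHc", "MpaLc", "Hc")) {
    sc <- make_scenario(nm)
    syn <- synth_peak_table(sc, noise_free_model(), replicates = 1)
    ab <- quantify_samples(syn$peaks, syn$meta, qpeptide_map(),
                           control = syn$control,
                           exclusions = c(VVDDILVEQGAQR = "miscleavage"))
    for (i in seq_len(nrow(syn$truth))) {
      got <- ab$copies_per_cell[ab$protein_id == syn$truth$protein_id[i]]
      want <- syn$truth$copies_per_cell[i]
      if (want == 0) expect_equal(got, 0)
      else expect_equal(got, want, tolerance = 1e-9)
    }
  }
})

test_that("background plus control subtraction still recovers exactly", {
  sc <- make_scenario("MpaLc")
  nm <- noise_model(cv = 0, background_frac = 0.005,
                    digestion_completeness = c(VVDDILVEQGAQR = 0.7))
  r <- recover_ratio(sc, nm, replicates = 1)
  expect_equal(r$ratio, 12, tolerance = 1e-9)
})

test_that("quantification is linear and exclusions are local", {
  sc <- make_scenario("MpaLc")
  syn <- synth_peak_table(sc, noise_free_model(), replicates = 1)
  ab1 <- quantify_samples(syn$peaks, syn$meta, qpeptide_map())
  doubled <- syn$peaks
  is_light <- doubled$channel == "light"
  doubled$area[is_light] <- doubled$area[is_light] * 2
  ab2 <- quantify_samples(doubled, syn$meta, qpeptide_map())
  expect_equal(ab2$copies_per_cell, 2 * ab1$copies_per_cell)

  ab3 <- quantify_samples(syn$peaks, syn$meta, qpeptide_map(),
                          exclusions = c(VVDDILVEQGAQR = "miscleavage"))
  keep <- ab1$protein_id != "atr2"
  expect_equal(ab3$copies_per_cell[keep], ab1$copies_per_cell[keep])
})

test_that("calibration is linear over the validated range", {
  amounts <- c(0.25, 1, 5, 25, 100, 500, 2500)
  cal <- fit_calibration(amounts, 0.012 * amounts)
  expect_equal(cal$r_squared, 1, tolerance = 1e-12)
  expect_equal(cal$range, c(0.25, 2500))
  expect_equal(cal$slope, 0.012)

  two <- fit_calibration(c(1, 10), c(0.5, 5))
  expect_equal(two$r_squared, 1)

  set.seed(19)
  noisy <- 0.012 * amounts * rlnorm(length(amounts), 0, 0.02)
  cal <- fit_calibration(amounts, noisy)
  expect_equal(cal$slope, 0.012, tolerance = 0.05)
  expect_error(fit_calibration(1, 2), "at least 2")
})

test_that("digestion time course plateau detection", {
  times <- c(1, 2, 4, 8, 16, 24)
  sig <- 1 - exp(-0.45 * times)
  res <- digestion_plateau(times, sig)
  expect_equal(res$time_h, 16)
  expect_true(res$plateau)

  res <- digestion_plateau(c(1, 2, 3), c(5, 5, 5))
  expect_equal(res$time_h, 2)
  res <- digestion_plateau(times, times * 3)
  expect_equal(res$time_h, 24)
  expect_false(res$plateau)
  expect_error(digestion_plateau(c(1, 2), c(1, 2)), "3 time points")
})

test_that("cells-in-digest helper scales harvest by aliquot fraction", {
  expect_equal(cells_in_digest(50, 50, 1000), 50 * 8e8 * 0.05)
  expect_error(cells_in_digest(50, 100, 50), "extracted_ug")
})
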