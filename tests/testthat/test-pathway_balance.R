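molar_total <- function(tc) {
  mw <- species_molar_mass()
  rowSums(sapply(names(mw), function(sp) tc[[sp]] / mw[[sp]]))
}

test_that("mixture ratio is the OD-weighted abundance quotient", {
  sc <- make_scenario("mix_100_1")
  r <- mixture_ratio(sc$components$a, sc$components$b,
                     sc$od[["a"]], sc$od[["b"]])
  expect_equal(r, 16)

  p <- enzyme_profile(p450 = 1200, cpr = 9000, cdh = 100)
  for (split in list(c(1, 1), c(3, 7), c(100, 1))) {
    expect_equal(mixture_ratio(p, p, split[1], split[2]), 12)
  }

  a <- enzyme_profile(p450 = 5000)
  b <- enzyme_profile(cdh = 2000)
  expect_equal(mixture_ratio(a, b, 10, 10) / 10,
               mixture_ratio(a, b, 10, 100))
  expect_equal(mixture_ratio(a, enzyme_profile(), 10, 10), Inf)
})

test_that("an enzyme-free cell leaves the substrate untouched", {
  tc <- simulate_bioconversion(enzyme_profile(), reaction_conditions())
  expect_equal(tc$limonene, rep(100, nrow(tc)))
  for (sp in c("carveol", "carvone", "dihydrocarveol", "dihydrocarvone")) {
    expect_equal(tc[[sp]], rep(0, nrow(tc)))
  }
})

test_that("total molar amount is conserved along every simulation", {
  for (nm in c("Mpa", "Hc", "MpaHc", "MpaLc", "mix_100_100", "mix_100_10",
               "mix_100_1")) {
    sc <- make_scenario(nm)
    tc <- simulate_bioconversion(sc$profile, sc$conditions)
    tot <- molar_total(tc)
    expect_lt(max(abs(tot - tot[1])) / tot[1], 1e-6)
  }
})

test_that("a stronger dihydrocarveol branch never increases carvone", {
  sc <- make_scenario("MpaLc")
  base <- unclass(default_kinetic_params())
  finals <- vapply(c(1, 2, 5), function(mult) {
    p <- base
    p$k_cdh_branch <- p$k_cdh_branch * mult
    tc <- simulate_bioconversion(sc$profile, sc$conditions,
                                 do.call(kinetic_params, p), step = 0.005)
    tc$carvone[nrow(tc)]
  }, numeric(1))
  expect_true(all(diff(finals) < 0))
})

test_that("without side reactions carveol+carvone equals limonene consumed", {
  sc <- make_scenario("MpaLc")
  base <- unclass(default_kinetic_params())
  base$k_cdh_branch <- 0
  profile <- sc$profile
  profile$endogenous <- 0
  tc <- simulate_bioconversion(profile, sc$conditions,
                               do.call(kinetic_params, base))
  mw <- species_molar_mass()
  fin <- tc[nrow(tc), ]
  consumed <- (100 - fin$limonene) / mw[["limonene"]]
  made <- fin$carveol / mw[["carveol"]] + fin$carvone / mw[["carvone"]]
  expect_equal(made, consumed, tolerance = 1e-8)
})

test_that("halving the integration step leaves endpoints unchanged", {
  for (nm in c("MpaLc", "MpaHc")) {
    sc <- make_scenario(nm)
    a <- simulate_bioconversion(sc$profile, sc$conditions, step = 0.005)
    b <- simulate_bioconversion(sc$profile, sc$conditions, step = 0.0025)
    expect_lt(abs(a$carvone[nrow(a)] - b$carvone[nrow(b)]) /
                b$carvone[nrow(b)], 1e-3)
  }
  expect_error(simulate_bioconversion(enzyme_profile(), step = 0.1), "0.01")
})

test_that("whole-cell activity is endpoint per hour per OD", {
  cond <- reaction_conditions(od600 = 5, duration_h = 2)
  tc <- tibble::tibble(time_h = c(0, 2), carveol = c(0, 24),
                       carvone = c(0, 0))
  expect_equal(whole_cell_activity(tc, "carveol", cond), 2.4)
  expect_equal(whole_cell_activity(tc, "carvone", cond), 0)
  expect_error(whole_cell_activity(tc, "limonene", cond), "not in timecourse")
  expect_error(reaction_conditions(duration_h = 0))
})

test_that("rate-constant calibration recovers known coefficients", {
  truth <- default_kinetic_params()
  # compact assay scenarios keep every objective evaluation cheap
  defs <- list(
    list(profile = enzyme_profile(p450 = 30000, cpr = 60000),
         conditions = reaction_conditions(od600 = 5, duration_h = 2),
         species = "carveol"),
    list(profile = enzyme_profile(cdh = 8000),
         conditions = reaction_conditions(od600 = 5, duration_h = 2,
                                          substrate = "carveol"),
         species = "carvone"),
    list(profile = enzyme_profile(p450 = 3000, cpr = 6000, cdh = 2000),
         conditions = reaction_conditions(od600 = 10, duration_h = 4),
         species = "carvone"),
    list(profile = enzyme_profile(p450 = 3000, cpr = 6000, cdh = 200),
         conditions = reaction_conditions(od600 = 10, duration_h = 4),
         species = "dihydrocarveol")
  )
  scenarios <- lapply(defs, function(d) {
    tc <- simulate_bioconversion(d$profile, d$conditions, truth)
    list(profile = d$profile, conditions = d$conditions,
         observed = stats::setNames(tc[[d$species]][nrow(tc)], d$species))
  })

  # starting at the truth: zero residual
  fit0 <- calibrate_rate_constants(scenarios, truth, step = 0.01,
                                   maxit = 500)
  expect_lt(max(abs(fit0$residuals)), 1e-3)

  # perturbed start: coefficients recovered within 1%
  start <- unclass(truth)
  for (k in c("k_p450", "k_cdh_carvone", "k_cdh_branch")) {
    start[[k]] <- start[[k]] * 1.3
  }
  fit <- calibrate_rate_constants(scenarios, do.call(kinetic_params, start),
                                  step = 0.01)
  for (k in c("k_p450", "k_cdh_carvone", "k_cdh_branch")) {
    expect_equal(fit$params[[k]], truth[[k]], tolerance = 0.01,
                 info = k)
  }

  expect_error(
    calibrate_rate_constants(scenarios[1], truth),
    "at least as many")
})

test_that("the simulated ratio-titer series peaks at ratio 16", {
  names <- c("MpaHc", "mix_100_100", "mix_100_10", "mix_100_1")
  pts <- do.call(rbind, lapply(names, function(nm) {
    sc <- make_scenario(nm)
    tc <- simulate_bioconversion(sc$profile, sc$conditions)
    tibble::tibble(ratio = sc$ratio_truth, titer = tc$carvone[nrow(tc)])
  }))
  res <- optimum_ratio_analysis(pts)
  expect_equal(res$optimal_ratio, 16)
  # the unbalanced high-CDH strain sits far below every mixture
  expect_lt(pts$titer[pts$ratio == 0.004], min(pts$titer[pts$ratio > 1]))
})

test_that("the ratio-titer optimum picks the maximal titer, ties upward", {
  pts <- tibble::tibble(ratio = c(0.004, 0.388, 3.4, 16),
                        titer = c(2.9, 28.4, 37.5, 38.0))
  res <- optimum_ratio_analysis(pts)
  expect_equal(res$optimal_ratio, 16)
  expect_equal(res$table$ratio[1], 16)

  expect_equal(optimum_ratio_analysis(pts[2, ])$optimal_ratio, 0.388)
  inc <- tibble::tibble(ratio = c(1, 2, 3), titer = c(1, 2, 3))
  expect_equal(optimum_ratio_analysis(inc)$optimal_ratio, 3)
  tie <- tibble::tibble(ratio = c(2, 8), titer = c(5, 5))
  expect_equal(optimum_ratio_analysis(tie)$optimal_ratio, 8)
  expect_error(optimum_ratio_analysis(tie[0, ]), "empty")
})
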