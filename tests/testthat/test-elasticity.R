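test_that("toy power-law model gives the closed-form elasticities", {
  # lambda = (p s_b s_n g / c)^(1/3): elasticity to p is exactly 1/3
  tp <- toy_params(r = 2.5, s_b = 0.9, nurse_m = 0.1, g = 0.5)
  pert <- perturbation_elasticity(tp, "p")
  expect_equal(pert$elasticity, 1 / 3, tolerance = 1e-8)
  anal <- analytic_elasticity(tp, "p")
  expect_equal(anal$elasticity, 1 / 3, tolerance = 1e-10)
  # ... and to c is exactly -1/3
  expect_equal(analytic_elasticity(tp, "c")$elasticity, -1 / 3,
               tolerance = 1e-10)
  expect_equal(perturbation_elasticity(tp, "c")$elasticity, -1 / 3,
               tolerance = 1e-8)
  # s_b sits on the same power law
  expect_equal(analytic_elasticity(tp, "s_b")$elasticity, 1 / 3,
               tolerance = 1e-10)
})

test_that("zero-valued parameters get elasticity 0 with an explicit flag", {
  p <- default_scenarios()$summer$params
  p0 <- beedemog:::set_param(p, "alpha_n", 0)
  for (f in list(perturbation_elasticity, analytic_elasticity)) {
    row <- f(p0, "alpha_n")
    expect_identical(row$elasticity, 0)
    expect_true(row$zero_param)
  }
})

test_that("elasticity is undefined when the growth rate is 0", {
  p0 <- beedemog:::set_param(default_scenarios()$winter$params, "p", 0)
  expect_error(perturbation_elasticity(p0, "gamma_f"), "undefined")
  expect_error(analytic_elasticity(p0, "gamma_f"), "undefined")
})

test_that("perturbation and analytic elasticities agree everywhere tested", {
  # all six mortality parameters at the three default scenarios
  for (sc in default_scenarios()) {
    for (pn in mortality_params) {
      e_num <- perturbation_elasticity(sc$params, pn)$elasticity
      e_an <- analytic_elasticity(sc$params, pn)$elasticity
      expect_lt(abs(e_num - e_an), 1e-4)
      expect_lte(e_num, 0)          # mortality cannot raise growth
    }
  }
  # and across random parameter sets, for all perturbable parameters
  set.seed(41)
  for (i in 1:10) {
    p <- random_valid_params()
    for (pn in c(mortality_params, "s_b", "g", "p", "c")) {
      e_num <- perturbation_elasticity(p, pn)$elasticity
      e_an <- analytic_elasticity(p, pn)$elasticity
      expect_lt(abs(e_num - e_an), 1e-4)
    }
  }
})

test_that("central differences are step-size robust", {
  p <- default_scenarios()$winter$params
  for (pn in c("beta_f", "gamma_n", "g")) {
    e3 <- perturbation_elasticity(p, pn, rel_step = 1e-3)$elasticity
    e5 <- perturbation_elasticity(p, pn, rel_step = 1e-5)$elasticity
    expect_lt(abs(e3 - e5), 1e-5)
  }
})

test_that("season comparison covers scenarios x parameters exactly once", {
  tab <- season_comparison()
  expect_identical(nrow(tab), 18L)
  expect_false(any(duplicated(tab[c("scenario", "param")])))
  expect_true(all(tab$abs_elasticity == abs(tab$elasticity)))
  expect_true(all(tab$elasticity <= 0))
  # deterministic: recomputing gives identical numbers
  expect_identical(tab$elasticity, season_comparison()$elasticity)
})

test_that("ordering report checks the six seasonal claims", {
  tab <- season_comparison()
  rep <- ordering_report(tab)
  expect_length(rep$checks, 6L)
  expect_true(rep$all_pass)

  # a flat table fails the strict inequalities
  flat <- tab
  flat$elasticity <- -1e-3
  flat$abs_elasticity <- 1e-3
  rep_flat <- ordering_report(flat)
  expect_false(rep_flat$all_pass)
  expect_false(any(vapply(rep_flat$checks, `[[`, TRUE, "verdict")))

  # an incomplete table is an error
  expect_error(ordering_report(tab[tab$scenario != "winter", ]), "cover")

  # JSON export carries all six verdicts
  path <- withr::local_tempfile(fileext = ".json")
  write_ordering_report(rep, path)
  parsed <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  expect_length(parsed$checks, 6L)
  expect_true(parsed$all_pass)
})

test_that("brood-survival sweep is consistent with the season table", {
  scen <- default_scenarios()
  tab <- season_comparison(scen)
  # a grid containing the winter default s_b reproduces the winter column
  sw <- brood_survival_sweep(scen$winter, sb_grid = c(0.8, scen$winter$params$s_b))
  at_default <- sw[sw$s_b == scen$winter$params$s_b, ]
  wi <- tab[tab$scenario == "winter", ]
  expect_equal(at_default$elasticity[match(wi$param, at_default$param)],
               wi$elasticity, tolerance = 1e-12)

  # a zero-growth grid point is flagged, not fatal
  dead <- beedemog:::set_param(scen$winter$params, "p", 0)
  sc0 <- season_scenario("winter", dead)
  sw0 <- brood_survival_sweep(sc0, sb_grid = c(0.6, 0.9))
  expect_true(all(sw0$lam_zero))
  expect_true(all(is.na(sw0$elasticity)))

  expect_error(brood_survival_sweep(scen$winter, sb_grid = c(0.9, 0.6)))
})

test_that("reduced brood survival raises forager-senescence elasticity only", {
  sw <- brood_survival_sweep(default_scenarios()$winter)
  by_param <- split(sw, sw$param)
  # |e(beta_f)| strictly increases as s_b decreases
  bf <- by_param$beta_f[order(by_param$beta_f$s_b), ]
  expect_true(all(diff(bf$abs_elasticity) < 0))
  # the other five parameters stay within 20% of their maxima
  for (pn in setdiff(mortality_params, "beta_f")) {
    x <- by_param[[pn]]$abs_elasticity
    expect_lt((max(x) - min(x)) / max(x), 0.2)
  }
})
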