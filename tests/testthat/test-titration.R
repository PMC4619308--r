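test_that("with no uncertainty the nadir distribution is degenerate at the
           deterministic simulation", {
  pop <- default_population()
  cfg <- titration_config(uncertainty = "none", n_sim = 20)
  fit <- fake_fit(pop)
  nd <- nadir_distribution(fit, pop, 5, cfg = cfg, cycle_start = 0,
                           seed = 1)
  expect_equal(length(nd$anc), 20)
  expect_true(all(nd$anc == nd$anc[1]))
  expect_true(all(nd$pc == nd$pc[1]))
  # matches an independent direct simulation of the same cycle
  tr <- simulate_marker(pop$pd_anc, pop$pk, standard_regimen(5),
                        seq(0, 6 * 168, by = 6))
  expect_equal(nd$anc[1], find_nadir(tr)$value, tolerance = 1e-3)
})

test_that("slope uncertainty alone leaves the zero-dose neutrophil nadir
           at baseline", {
  pop <- default_population()
  free <- names(pop$omega)[pop$omega > 0]
  cov <- diag(1e-12, length(free))
  dimnames(cov) <- list(free, free)
  cov["slope_anc", "slope_anc"] <- 0.3^2
  fit <- fake_fit(pop, cov = cov)
  cfg <- titration_config(n_sim = 50)
  nd <- nadir_distribution(fit, pop, 0, cfg = cfg, cycle_start = 0,
                           seed = 4)
  expect_lt(max(abs(nd$anc - 3240)) / 3240, 1e-4)
})

test_that("the percentile nadir is monotone non-increasing in dose and the
           selected dose is certified at the threshold boundary", {
  pop <- default_population()
  study <- generate_synthetic_study(pop, 1, seed = 61, n_cycles = 1)
  fit <- suppressWarnings(fit_individual_map(study[[1]], pop, n_starts = 1))
  dec <- select_cycle_dose(fit, previous_dose = 40, pop,
                           titration_config(), seed = 9)
  tab <- dec$table
  expect_true(all(diff(tab$anc_q) <= 1e-9))
  expect_true(all(diff(tab$pc_q) <= 1e-9))
  if (!dec$no_safe_dose && !dec$cap_applied) {
    sel_row <- tab[tab$dose == dec$selected, ]
    expect_true(sel_row$qualifies)
    nxt <- tab[match(dec$selected, tab$dose) + 1, ]
    if (!is.na(nxt$dose)) {
      expect_false(nxt$qualifies)
      expect_true(dec$limiting_marker %in% c("ANC", "PC"))
    }
  }
})

test_that("the 150% dose cap binds exactly when the model would allow
           more", {
  pop <- default_population()
  # no drug effect at all: every dose is safe
  pk <- pop$pk
  anc0 <- pd_parameters(0.0132, 0, 3240, 0.193, marker = "ANC")
  pc0 <- pd_parameters(0.0244, 0, 49200, 0.304, 55000, 0.000530,
                       marker = "PC")
  pop0 <- population_model(pk, anc0, pc0)
  cfg <- titration_config(uncertainty = "none", n_sim = 5)
  fit <- fake_fit(pop0)
  dec <- select_cycle_dose(fit, previous_dose = 5, pop0, cfg, seed = 1,
                           cycle_start = 0)
  expect_equal(dec$selected, 7.5)  # 1.5 x 5
  expect_true(dec$cap_applied)
  expect_false(dec$no_safe_dose)
  # with a large previous dose the grid maximum is reached uncapped
  dec2 <- select_cycle_dose(fit, previous_dose = 40, pop0, cfg, seed = 1,
                            cycle_start = 0)
  expect_equal(dec2$selected, 15)
  expect_false(dec2$cap_applied)
  # an off-grid cap value is allowed: 1.5 x 5.5 = 8.25
  dec3 <- select_cycle_dose(fit, previous_dose = 5.5, pop0, cfg, seed = 1,
                            cycle_start = 0)
  expect_equal(dec3$selected, 8.25)
})

test_that("bisection search selects exactly the same dose as the full
           grid scan", {
  pop <- default_population()
  set.seed(17)
  for (i in 1:12) {
    ind <- draw_individual(pop, seed = 1700 + i)
    popi <- population_model(ind$pk, ind$pd_anc, ind$pd_pc,
                             sigma2_pk_prop = 0.441,
                             sigma2_anc_add = 754, sigma2_pc_add = 25000)
    fit <- fake_fit(popi)
    cfg_g <- titration_config(uncertainty = "none", n_sim = 2,
                              search = "grid")
    cfg_b <- titration_config(uncertainty = "none", n_sim = 2,
                              search = "bisect")
    dg <- select_cycle_dose(fit, 40, popi, cfg_g, seed = 1, cycle_start = 0)
    db <- select_cycle_dose(fit, 40, popi, cfg_b, seed = 1, cycle_start = 0)
    expect_equal(db$selected, dg$selected)
    expect_equal(db$no_safe_dose, dg$no_safe_dose)
  }
})

test_that("the 500-replicate percentile is consistent with a larger
           Monte-Carlo run", {
  pop <- default_population()
  study <- generate_synthetic_study(pop, 1, seed = 71, n_cycles = 1)
  fit <- suppressWarnings(fit_individual_map(study[[1]], pop, n_starts = 1))
  q500 <- stats::quantile(
    nadir_distribution(fit, pop, 5, titration_config(), seed = 3)$anc,
    0.25, type = 7)
  big <- nadir_distribution(fit, pop, 5, titration_config(n_sim = 4000),
                            seed = 4)$anc
  qbig <- stats::quantile(big, 0.25, type = 7)
  # tolerance: 4 standard errors of the 500-replicate quantile, with the
  # density at the quantile estimated from the large run
  f_hat <- stats::density(big)
  fq <- stats::approx(f_hat$x, f_hat$y, xout = qbig)$y
  se <- sqrt(0.25 * 0.75 / 500) / fq
  expect_lt(abs(q500 - qbig), 4 * se)
})

test_that("cohort dose estimation reduces to the typical subject without
           BSV and hits the grid maximum for a toxicity-free population", {
  pop <- default_population()
  pop_fixed <- population_model(pop$pk, pop$pd_anc, pop$pd_pc,
                                sigma2_pk_prop = 0.441,
                                sigma2_anc_add = 754,
                                sigma2_pc_add = 25000)
  cfg <- titration_config(uncertainty = "none", n_sim = 5)
  cde <- estimate_cohort_start_dose(pop_fixed, cfg, seed = 2)
  fit <- fake_fit(pop_fixed)
  typ <- select_cycle_dose(fit, 40, pop_fixed, cfg, seed = 2,
                           cycle_start = 0)
  expect_equal(cde$selected, typ$selected)
  expect_false(cde$cap_applied)
  # no drug effect anywhere: the full grid qualifies
  anc0 <- pd_parameters(0.0132, 0, 3240, 0.193, marker = "ANC")
  pc0 <- pd_parameters(0.0244, 0, 49200, 0.304, 55000, 0.000530,
                       marker = "PC")
  pop0 <- population_model(pop$pk, anc0, pc0)
  cde0 <- estimate_cohort_start_dose(pop0, cfg, seed = 2)
  expect_equal(cde0$selected, 15)
})

test_that("a cohort starting dose from a small fitted population lands
           within one grid step of a larger Monte-Carlo answer", {
  pop <- default_population()
  study <- generate_synthetic_study(pop, 3, seed = 81, n_cycles = 1)
  pfit <- suppressWarnings(fit_population_two_stage(study, pop,
                                                    rtol = 1e-5,
                                                    atol = 0.1))
  sel500 <- sapply(5:8, function(s)
    estimate_cohort_start_dose(pfit, titration_config(), seed = s)$selected)
  d2k <- estimate_cohort_start_dose(pfit, titration_config(n_sim = 4000),
                                    seed = 9)
  # individual 500-replicate runs scatter around the large-n answer; their
  # median lands within one grid step
  expect_lte(abs(stats::median(sel500) - d2k$selected), 0.5)
})

test_that("titration configuration validates its inputs", {
  expect_error(titration_config(percentile = 60), "percentile")
  expect_error(titration_config(cap_fraction = 1), "cap_fraction")
  expect_error(titration_config(dose_grid = c(2, 1)), "ascending")
  pop <- default_population()
  fit <- fake_fit(pop)
  expect_error(select_cycle_dose(fit, 0, pop, seed = 1), "previous_dose")
})
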