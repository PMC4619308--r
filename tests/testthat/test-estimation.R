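# a small noise-free subject at known parameters, reused across tests
make_noisefree_subject <- function(pop, eta = NULL, n_pd = 8) {
  ind <- individual_from_eta(pop, if (is.null(eta)) numeric() else eta)
  reg <- standard_regimen(5)
  pk_t <- c(0, 20, 40, 60, 90, 120, 180) / 60
  pd_t <- seq(0, 7 * 168, length.out = n_pd)
  conc <- predict_concentration(ind$pk, reg, pk_t)
  cnt <- myelotitr:::sim_counts(ind, reg, sort(unique(c(0, pd_t))),
                                rtol = 1e-8, atol = 1e-6)
  ix <- match(pd_t, cnt$times)
  obs <- rbind(
    data.frame(time = pk_t, kind = "conc", value = conc, bql = conc < 0.5),
    data.frame(time = pd_t, kind = "ANC", value = cnt$anc[ix], bql = FALSE),
    data.frame(time = pd_t, kind = "PC", value = cnt$pc[ix], bql = FALSE))
  subject_data(obs, reg, bsa = 1, id = 1L)
}

test_that("the -2 log-likelihood has the stated closed form", {
  pop <- default_population()
  d <- make_noisefree_subject(pop)
  ind <- individual_from_eta(pop)
  # noise-free data at the evaluated parameters: only the normalisation
  # constant remains
  obs <- d$observations
  used <- !(obs$bql & obs$kind == "conc")
  ipred <- obs$value
  v <- ifelse(obs$kind == "conc", ipred^2 * 0.441,
              ifelse(obs$kind == "ANC", 754, 25000))
  expect_equal(neg2_log_likelihood(ind, d, pop),
               sum(log(2 * pi * v[used])), tolerance = 1e-6)
  # single ANC observation: (y - p)^2 / sigma2 + log(2 pi sigma2)
  y <- 3000; p <- 3240
  d1 <- subject_data(data.frame(time = 7 * 24, kind = "ANC", value = y,
                                bql = FALSE), standard_regimen(0))
  expect_equal(neg2_log_likelihood(ind, d1, pop),
               (y - p)^2 / 754 + log(2 * pi * 754), tolerance = 1e-9)
  # perturbing any parameter away from truth increases the objective
  base_val <- neg2_log_likelihood(ind, d, pop)
  for (par in c("cl", "slope_anc", "base_anc", "slope_pc")) {
    for (shift in c(-0.15, 0.15)) {
      ind_p <- individual_from_eta(pop, stats::setNames(shift, par))
      expect_gt(neg2_log_likelihood(ind_p, d, pop), base_val)
    }
  }
})

test_that("the fast optimisation objective matches the reference
           likelihood", {
  pop <- default_population()
  study <- generate_synthetic_study(pop, 1, seed = 21, n_cycles = 1)
  d <- study[[1]]
  free <- names(pop$omega)[pop$omega > 0]
  fast <- myelotitr:::make_fast_objective(d, pop, free, "drop", 0.5,
                                          1e-6, 0.01)
  set.seed(3)
  for (i in 1:4) {
    eta <- stats::setNames(stats::rnorm(length(free), 0, 0.2), free)
    expect_equal(fast(eta),
                 myelotitr:::map_objective(eta, free, d, pop, pop$omega,
                                           "drop", 0.5, 1e-6, 0.01),
                 tolerance = 1e-10)
  }
})

test_that("MAP estimation collapses to the typical values under an
           infinitely tight prior and recovers truth on noise-free data", {
  pop <- default_population()
  pop0 <- population_model(pop$pk, pop$pd_anc, pop$pd_pc,
                           sigma2_pk_prop = 0.441, sigma2_anc_add = 754,
                           sigma2_pc_add = 25000)
  d <- make_noisefree_subject(pop)
  f0 <- fit_individual_map(d, pop0)
  expect_equal(f0$individual$pk$cl, 87.8)
  expect_equal(f0$individual$pd_anc$slope, 0.263)
  # exact identifiability: noise-free subject away from typical values,
  # fitted under a near-flat prior so the likelihood determines the mode
  eta_true <- c(cl = 0.25, slope_anc = -0.3, base_anc = 0.2)
  d2 <- make_noisefree_subject(pop, eta_true, n_pd = 16)
  pop_weak <- population_model(pop$pk, pop$pd_anc, pop$pd_pc,
                               bsv_cv = c(cl = 1e4, slope_anc = 1e4,
                                          base_anc = 1e4),
                               sigma2_pk_prop = 0.441,
                               sigma2_anc_add = 754,
                               sigma2_pc_add = 25000)
  f2 <- suppressWarnings(fit_individual_map(d2, pop_weak, n_starts = 1))
  expect_equal(f2$eta[["cl"]], 0.25, tolerance = 0.02)
  expect_equal(f2$eta[["slope_anc"]], -0.3, tolerance = 0.05)
  expect_equal(f2$eta[["base_anc"]], 0.2, tolerance = 0.02)
  # accepted objective values decrease monotonically along the trace
  expect_true(all(diff(f2$trace) <= 0))
  expect_false(is.null(f2$cov))
  expect_true(all(eigen(f2$cov, symmetric = TRUE,
                        only.values = TRUE)$values > 0))
})

test_that("freeing a nested parameter never worsens the penalised
           objective", {
  pop <- default_population()
  study <- generate_synthetic_study(pop, 1, seed = 31, n_cycles = 1)
  d <- study[[1]]
  free_all <- names(pop$omega)[pop$omega > 0]
  f_red <- suppressWarnings(
    fit_individual_map(d, pop, free = setdiff(free_all, "gamma_anc"),
                       n_starts = 1))
  f_full <- suppressWarnings(
    fit_individual_map(d, pop, free = free_all, n_starts = 1,
                       init = f_red$eta))
  expect_gte(f_red$objective - f_full$objective, -1e-6)
})

test_that("individual recovery improves with sampling density", {
  pop <- default_population()
  designs <- list(
    sparse = study_sampling_design(pk_times_min = c(0, 60, 180),
                                   pd_interval_days = 14),
    rich = study_sampling_design())
  errs <- sapply(designs, function(ds) {
    e <- sapply(1:6, function(i) {
      study <- generate_synthetic_study(pop, 1, seed = 500 + i,
                                        design = ds, n_cycles = 1)
      tru <- attr(study, "individuals")[[1]]
      f <- suppressWarnings(fit_individual_map(study[[1]], pop,
                                               n_starts = 1))
      abs(log(f$individual$pk$cl / tru$pk$cl))
    })
    stats::median(e)
  })
  expect_lte(errs[["rich"]], errs[["sparse"]])
})

test_that("two-stage population refitting recovers a shifted truth and
           degenerates correctly", {
  pop <- default_population()
  # identical noise-free subjects under a clearance-only BSV model:
  # the BSV estimate collapses and the typical value moves to the truth
  pop_cl <- population_model(pop$pk, pop$pd_anc, pop$pd_pc,
                             bsv_cv = c(cl = 21.4),
                             sigma2_pk_prop = 0.441, sigma2_anc_add = 754,
                             sigma2_pc_add = 25000)
  subs <- replicate(3, make_noisefree_subject(pop_cl, c(cl = 0.1)),
                    simplify = FALSE)
  pf <- suppressWarnings(
    fit_population_two_stage(subs, pop_cl, update_sigma = FALSE))
  expect_equal(pf$pop$pk$cl, 87.8 * exp(0.1), tolerance = 0.02)
  expect_lt(pf$pop$omega[["cl"]], 0.05)
  expect_error(fit_population_two_stage(subs[1:2], pop_cl), "3 subjects")
  # full model has more BSV parameters than these 3 subjects support
  expect_warning(fit_population_two_stage(subs, pop, update_sigma = FALSE,
                                          max_iter = 1),
                 "fewer subjects")
})

test_that("below-quantification-limit concentrations are dropped or
           censored per the M3 option", {
  pop <- default_population()
  ind <- individual_from_eta(pop)
  reg <- standard_regimen(5, n_days = 1)
  obs <- data.frame(time = c(1, 10), kind = "conc",
                    value = c(predict_concentration(ind$pk, reg, 1), 0.2),
                    bql = c(FALSE, TRUE))
  d <- subject_data(obs, reg)
  drop_ll <- neg2_log_likelihood(ind, d, pop, bql_method = "drop")
  m3_ll <- neg2_log_likelihood(ind, d, pop, bql_method = "m3")
  ip1 <- obs$value[1]
  expect_equal(drop_ll, log(2 * pi * ip1^2 * 0.441), tolerance = 1e-9)
  ip2 <- predict_concentration(ind$pk, reg, 10)
  cens <- -2 * stats::pnorm(0.5, ip2, abs(ip2) * sqrt(0.441), log.p = TRUE)
  expect_equal(m3_ll, drop_ll + cens, tolerance = 1e-6)
})
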