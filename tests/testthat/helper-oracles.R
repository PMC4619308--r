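# shared fixtures and independent oracles (deSolve-based) for the tests

table3_pk <- function() pk_parameters(87.8, 18.5, 22.9, 13.1)
table3_anc <- function() pd_parameters(0.0132, 0.263, 3240, 0.193,
                                       marker = "ANC")
table3_pc <- function() pd_parameters(0.0244, 0.0656, 49200, 0.304,
                                      55000, 0.000530, marker = "PC")

# two-compartment infusion amounts integrated with lsoda; independent of
# the package's closed form and of its compiled integrator
pk_ode_oracle <- function(pk, reg, times) {
  ev <- as.data.frame(reg)
  bsa <- if (nrow(ev)) ev$bsa[1] else 1
  cl <- pk$cl * bsa; vc <- pk$vc * bsa
  q <- pk$q * bsa; vp <- pk$vp * bsa
  rate_at <- function(t)
    sum(ifelse(t >= ev$start_time & t < ev$start_time + ev$duration,
               ev$dose_per_bsa * 1000 * ev$bsa / ev$duration, 0))
  rhs <- function(t, y, p)
    list(c(rate_at(t) - (cl / vc) * y[1] - (q / vc) * y[1] + (q / vp) * y[2],
           (q / vc) * y[1] - (q / vp) * y[2]))
  brk <- sort(unique(c(times, ev$start_time, ev$start_time + ev$duration)))
  out <- deSolve::lsoda(c(0, 0), brk, rhs, NULL, rtol = 1e-10, atol = 1e-10)
  out[match(times, brk), 2] / vc
}

# transit-feedback trajectory via lsoda with the R right-hand side
pd_lsoda_oracle <- function(pd, pk, reg, grid, rtol = 1e-9) {
  rhs <- function(t, y, p) {
    conc <- predict_concentration(pk, reg, t)
    list(pd_derivatives(y, t, pd, conc))
  }
  ev <- as.data.frame(reg)
  brk <- sort(unique(c(grid, ev$start_time, ev$start_time + ev$duration)))
  out <- deSolve::lsoda(rep(pd$base, 5), brk, rhs, NULL, rtol = rtol,
                        atol = 1e-8)
  out[match(grid, brk), 6]
}

# a hand-built individual fit object (point estimate + covariance) for
# exercising the titration machinery without running the optimiser
fake_fit <- function(pop, eta = NULL, cov = NULL,
                     events = data.frame(start_time = numeric(),
                                         duration = numeric(),
                                         dose_per_bsa = numeric(),
                                         bsa = numeric())) {
  free <- names(pop$omega)[pop$omega > 0]
  eta_full <- stats::setNames(numeric(length(free)), free)
  if (!is.null(eta)) eta_full[names(eta)] <- eta
  ind <- individual_from_eta(pop, eta_full)
  structure(list(individual = ind, eta = eta_full, objective = 0,
                 convergence = TRUE, cov = cov, residuals = NULL,
                 trace = numeric(), free = free, pop = pop,
                 data = list(events = events, bsa = 1, id = 0L)),
            class = "mt_fit")
}
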