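# Individual predictions at the observation times of a subject_data object.
# Concentrations come from the closed-form PK solution; counts from one
# joint integration of both transit systems.
predict_observations <- function(indiv, data, rtol = 1e-6, atol = 0.01) {
  obs <- data$observations
  ipred <- numeric(nrow(obs))
  reg <- regimen_of(data)
  is_c <- obs$kind == "conc"
  if (any(is_c)) {
    ord <- order(obs$time[is_c])
    tt <- obs$time[is_c][ord]
    cc <- predict_concentration(indiv$pk, reg, tt)
    ipred[which(is_c)[ord]] <- cc
  }
  is_pd <- !is_c
  if (any(is_pd)) {
    tt <- sort(unique(c(0, obs$time[is_pd])))
    counts <- sim_counts(indiv, reg, tt, rtol = rtol, atol = atol)
    ix <- match(obs$time[is_pd], counts$times)
    ipred[is_pd] <- ifelse(obs$kind[is_pd] == "ANC", counts$anc[ix],
                           counts$pc[ix])
  }
  ipred
}

#' Gaussian -2 log-likelihood of a subject's data
#'
#' Residual variance is `IPRED^2 sigma2_pk_prop` for concentrations and the
#' marker's additive variance for counts, with individual predictions from
#' the PK closed form and the integrated transit model at the individual's
#' parameters. Below-quantification-limit concentrations are dropped by
#' default or treated by a censored-likelihood (M3-style) term.
#'
#' @param indiv [individual_from_eta()] result (realised parameters)
#' @param data a [subject_data()]
#' @param pop [population_model()] supplying the residual variances
#' @param bql_method `"drop"` or `"m3"`
#' @param lloq quantification limit for the M3 term, ng/mL
#' @param rtol,atol integration tolerances for the count predictions
#' @return scalar -2 log-likelihood
#' @export
neg2_log_likelihood <- function(indiv, data, pop, bql_method = c("drop", "m3"),
                                lloq = 0.5, rtol = 1e-6, atol = 0.01) {
  bql_method <- match.arg(bql_method)
  obs <- data$observations
  if (nrow(obs) == 0) stop_input("no observations")
  ipred <- predict_observations(indiv, data, rtol, atol)
  v <- ifelse(obs$kind == "conc", ipred^2 * pop$sigma2_pk_prop,
              ifelse(obs$kind == "ANC", pop$sigma2_anc_add,
                     pop$sigma2_pc_add))
  ll <- 0
  use <- rep(TRUE, nrow(obs))
  bql <- obs$bql & obs$kind == "conc"
  if (any(bql)) {
    use[bql] <- FALSE
    if (bql_method == "m3") {
      sd_b <- sqrt(v[bql])
      ll <- ll - 2 * sum(stats::pnorm(lloq, ipred[bql], sd_b, log.p = TRUE))
    }
  }
  if (any(v[use] <= 0))
    stop_input("zero residual variance for an observed data type")
  r <- obs$value[use] - ipred[use]
  ll + sum(log(2 * pi * v[use]) + r^2 / v[use])
}

map_objective <- function(eta, free, data, pop, omega, bql_method, lloq,
                          rtol, atol) {
  names(eta) <- free
  indiv <- individual_from_eta(pop, eta, bsa = data$bsa, id = data$id)
  n2ll <- tryCatch(
    neg2_log_likelihood(indiv, data, pop, bql_method, lloq, rtol, atol),
    error = function(e) NA_real_)
  if (!is.finite(n2ll)) return(1e10 + sum(eta^2))  # integration failure
  n2ll + sum(eta^2 / omega[free]^2)
}

# Precomputed MAP objective used in the optimisation hot loop; numerically
# identical to map_objective() (asserted in the test suite) but avoids
# rebuilding parameter objects and data frames at every evaluation.
make_fast_objective <- function(data, pop, free, bql_method, lloq, rtol,
                                atol) {
  ev <- events_matrix(dose_regimen(data$events))
  obs <- data$observations
  bsa <- data$bsa
  typ <- typical_vector(pop)
  om2 <- pop$omega[free]^2
  ncmt <- pop$pk$n_compartments
  s2pk <- pop$sigma2_pk_prop
  is_c <- obs$kind == "conc"
  bql <- obs$bql & is_c
  use_c <- which(is_c & !bql)
  use_c <- use_c[order(obs$time[use_c])]
  ct <- obs$time[use_c]
  cdv <- obs$value[use_c]
  m3 <- bql_method == "m3"
  bt <- sort(obs$time[bql])
  is_pd <- which(!is_c)
  pt <- sort(unique(c(0, obs$time[is_pd])))
  pd_ix <- match(obs$time[is_pd], pt)
  pd_anc <- obs$kind[is_pd] == "ANC"
  pd_dv <- obs$value[is_pd]
  pd_v <- ifelse(pd_anc, pop$sigma2_anc_add, pop$sigma2_pc_add)
  if (length(is_pd) && any(pd_v <= 0))
    stop_input("zero residual variance for an observed data type")
  function(eta) {
    v <- typ
    v[free] <- v[free] * exp(eta)
    pkv <- c(ncmt, v[["cl"]], v[["vc"]], v[["q"]], v[["vp"]]) *
      c(1, bsa, bsa, bsa, bsa)
    ll <- 0
    if (length(ct) || length(bt)) {
      cc <- cpp_conc(c(ct, bt), ev, pkv)
      ic <- cc[seq_along(ct)]
      vv <- ic^2 * s2pk
      if (any(vv <= 0)) return(1e10 + sum(eta^2))
      ll <- ll + sum(log(2 * pi * vv) + (cdv - ic)^2 / vv)
      if (m3 && length(bt)) {
        ib <- cc[length(ct) + seq_along(bt)]
        ll <- ll - 2 * sum(stats::pnorm(lloq, ib, abs(ib) * sqrt(s2pk),
                                        log.p = TRUE))
      }
    }
    if (length(is_pd)) {
      pdm <- rbind(c(v[["ktr_anc"]], v[["slope_anc"]], v[["base_anc"]],
                     v[["gamma_anc"]], 0, 0),
                   c(v[["ktr_pc"]], v[["slope_pc"]], v[["base_pc"]],
                     v[["gamma_pc"]], v[["imp"]], v[["imk"]]))
      st <- tryCatch(
        cpp_simulate(pt, ev, pkv, pdm,
                     c(rep(v[["base_anc"]], 5), rep(v[["base_pc"]], 5)),
                     rtol, atol),
        error = function(e) NULL)
      if (is.null(st)) return(1e10 + sum(eta^2))
      ip <- ifelse(pd_anc, st[pd_ix, 5], st[pd_ix, 10])
      ll <- ll + sum(log(2 * pi * pd_v) + (pd_dv - ip)^2 / pd_v)
    }
    ll + sum(eta^2 / om2)
  }
}

#' Empirical-Bayes (MAP) fit of one subject
#'
#' Minimises the penalised objective
#' `-2 logLik + sum_j eta_j^2 / omega_j^2` over the log-scale deviations of
#' the parameters with estimated between-subject variability (all other
#' parameters stay at their typical values). Optimisation is Nelder-Mead on
#' the unconstrained log scale, with optional multi-start; ties are broken
#' by the lowest objective and then lexicographically smallest deviation
#' vector. The curvature of the objective at the optimum provides an
#' approximate covariance of the estimates.
#'
#' @param data a [subject_data()]
#' @param pop [population_model()] acting as the prior
#' @param init optional starting point: a named eta vector or an earlier
#'   `mt_fit` (warm start)
#' @param free parameter names to estimate; defaults to all parameters with
#'   positive BSV
#' @param n_starts number of optimisation starts (first at `init`/zero,
#'   remainder jittered)
#' @param seed seed for the start jitter
#' @param hessian compute the curvature-based covariance
#' @param bql_method,lloq below-quantification-limit handling, see
#'   [neg2_log_likelihood()]
#' @param rtol,atol integration tolerances used inside the objective
#' @param control passed to [stats::optim()] (`maxit` default 500,
#'   `reltol` 1e-8)
#' @return an `mt_fit`: realised `individual`, `eta`, `objective`,
#'   `convergence` flag, approximate `cov` (free parameters, log scale),
#'   per-observation `residuals`, and the accepted-objective `trace`
#' @export
fit_individual_map <- function(data, pop, init = NULL, free = NULL,
                               n_starts = 5, seed = 1L, hessian = TRUE,
                               bql_method = "drop", lloq = 0.5,
                               rtol = 1e-6, atol = 0.01, control = list()) {
  if (nrow(data$observations) == 0) stop_input("no observations to fit")
  omega <- pop$omega
  free <- free %||% names(omega)[omega > 0]
  if (!length(free)) {  # infinite prior precision everywhere
    indiv <- individual_from_eta(pop, bsa = data$bsa, id = data$id)
    return(structure(list(individual = indiv, eta = indiv$eta * 0,
                          objective = neg2_log_likelihood(
                            indiv, data, pop, bql_method, lloq, rtol, atol),
                          convergence = TRUE, cov = NULL,
                          residuals = fit_residuals(indiv, data, pop, rtol,
                                                    atol),
                          trace = numeric(), free = character(),
                          pop = pop, data = data),
                     class = "mt_fit"))
  }
  ctl <- utils::modifyList(list(maxit = 1000, reltol = 1e-8, restarts = 5),
                           control)
  eta0 <- stats::setNames(numeric(length(free)), free)
  if (inherits(init, "mt_fit")) {
    common <- intersect(free, names(init$eta))
    eta0[common] <- init$eta[common]
  } else if (!is.null(init)) {
    common <- intersect(free, names(init))
    eta0[common] <- init[common]
  }
  starts <- list(eta0)
  if (n_starts > 1) {
    jit <- with_seed(seed, lapply(seq_len(n_starts - 1), function(i)
      eta0 + stats::rnorm(length(free), 0, 0.5 * omega[free])))
    starts <- c(starts, jit)
  }
  fast_obj <- make_fast_objective(data, pop, free, bql_method, lloq, rtol,
                                  atol)
  trace_env <- new.env()
  trace_env$best <- Inf
  trace_env$trace <- numeric()
  obj <- function(eta) {
    val <- fast_obj(eta)
    if (val < trace_env$best) {
      trace_env$best <- val
      trace_env$trace <- c(trace_env$trace, val)
    }
    val
  }
  best <- NULL
  for (s in starts) {
    # Nelder-Mead with simplex restarts: the simplex tends to collapse
    # prematurely on the narrow curved ridge that the near-noiseless count
    # data creates between clearance and the drug-effect slopes, and a
    # restart at the incumbent re-expands it
    par <- s
    prev <- Inf
    fit <- NULL
    for (r in seq_len(ctl$restarts)) {
      o <- stats::optim(par, obj, method = "Nelder-Mead",
                        control = ctl[c("maxit", "reltol")])
      fit <- o
      if (prev - o$value < max(1e-6, abs(o$value) * 1e-8)) break
      par <- o$par
      prev <- o$value
    }
    better <- is.null(best) || fit$value < best$value - 1e-12 ||
      (abs(fit$value - best$value) <= 1e-12 &&
         isTRUE(all(fit$par <= best$par)) && any(fit$par < best$par))
    if (better) best <- fit
  }
  if (best$convergence != 0)
    warning("MAP optimisation did not converge; best point returned")
  eta_hat <- stats::setNames(best$par, free)
  indiv <- individual_from_eta(pop, eta_hat, bsa = data$bsa, id = data$id)
  cov <- NULL
  if (hessian) {
    h <- tryCatch(stats::optimHess(best$par, obj), error = function(e) NULL)
    if (!is.null(h)) {
      # objective is -2 log posterior, so covariance is 2 H^-1
      cov <- tryCatch(2 * solve(h), error = function(e) NULL)
      if (!is.null(cov)) {
        ev <- eigen(cov, symmetric = TRUE, only.values = TRUE)$values
        if (any(ev <= 0)) cov <- NULL
      }
    }
    if (!is.null(cov)) dimnames(cov) <- list(free, free)
  }
  structure(list(individual = indiv, eta = eta_hat, objective = best$value,
                 convergence = best$convergence == 0, cov = cov,
                 residuals = fit_residuals(indiv, data, pop, rtol, atol),
                 trace = trace_env$trace, free = free, pop = pop,
                 data = data),
            class = "mt_fit")
}

fit_residuals <- function(indiv, data, pop, rtol = 1e-6, atol = 0.01) {
  obs <- data$observations
  ipred <- predict_observations(indiv, data, rtol, atol)
  sdv <- ifelse(obs$kind == "conc", abs(ipred) * sqrt(pop$sigma2_pk_prop),
                ifelse(obs$kind == "ANC", sqrt(pop$sigma2_anc_add),
                       sqrt(pop$sigma2_pc_add)))
  data.frame(time = obs$time, kind = obs$kind, dv = obs$value,
             ipred = ipred, res = obs$value - ipred,
             wres = (obs$value - ipred) / sdv, bql = obs$bql)
}

#' @export
print.mt_fit <- function(x, ...) {
  cat(sprintf("<mt_fit> id %s: objective %.3f, %sconverged\n",
              x$data$id, x$objective, if (x$convergence) "" else "NOT "))
  if (length(x$eta))
    cat("  eta:", paste(sprintf("%s=%.3f", names(x$eta), x$eta),
                        collapse = ", "), "\n")
  invisible(x)
}

# replace selected typical values / omegas / sigmas of a population model
pop_update <- function(pop, typical = NULL, omega = NULL,
                       sigma2_pk_prop = NULL, sigma2_anc_add = NULL,
                       sigma2_pc_add = NULL) {
  v <- typical_vector(pop)
  if (!is.null(typical)) v[names(typical)] <- typical
  p <- params_from_vector(v, pop$pk$n_compartments)
  om <- pop$omega
  if (!is.null(omega)) om[names(omega)] <- omega
  new <- population_model(p$pk, p$pd_anc, p$pd_pc,
                          sigma2_pk_prop = sigma2_pk_prop %||%
                            pop$sigma2_pk_prop,
                          sigma2_anc_add = sigma2_anc_add %||%
                            pop$sigma2_anc_add,
                          sigma2_pc_add = sigma2_pc_add %||%
                            pop$sigma2_pc_add,
                          cv_convention = pop$cv_convention)
  new$omega <- om
  new
}

#' Two-stage population re-estimation
#'
#' Stage 1 fits every subject by penalised maximum likelihood
#' ([fit_individual_map()] against the current population values); stage 2
#' sets the typical value of each variability parameter to the geometric
#' mean of the individual estimates, the BSV variance to the sample
#' variance of their logs, and re-estimates the residual variances from the
#' pooled residuals. The two stages iterate to a fixed point. This is the
#' package's deliberately simple population-refitting route, used for
#' cohort dose estimation and parameter-recovery testing; MAP shrinkage
#' makes the resulting BSV variances conservative (biased low), which is
#' documented in the methods vignette.
#'
#' @param datasets list of [subject_data()] (at least 3 subjects)
#' @param init starting [population_model()]
#' @param max_iter maximum stage-1/stage-2 iterations
#' @param tol convergence tolerance on the maximum absolute change of the
#'   log typical values
#' @param fit_starts optimisation starts per subject fit
#' @param update_sigma re-estimate the residual variances from pooled
#'   residuals
#' @param ... passed to [fit_individual_map()]
#' @return an `mt_pop_fit`: the refitted `pop`, the final per-subject
#'   `fits`, `n_iter`, `converged`, and the summed `objective`
#' @export
fit_population_two_stage <- function(datasets, init, max_iter = 4,
                                     tol = 0.01, fit_starts = 1,
                                     update_sigma = TRUE, ...) {
  if (length(datasets) < 3) stop_input("need at least 3 subjects")
  pop <- init
  free <- names(pop$omega)[pop$omega > 0]
  est_omega <- length(datasets) >= length(free)
  if (!est_omega)
    warning("fewer subjects than parameters with BSV; ",
            "keeping the initial BSV variances")
  fits <- NULL
  converged <- FALSE
  it <- 0
  for (it in seq_len(max_iter)) {
    free_i <- names(pop$omega)[pop$omega > 0]
    if (!length(free_i)) { converged <- TRUE; break }
    fits <- lapply(datasets, function(d)
      fit_individual_map(d, pop, n_starts = fit_starts, hessian = FALSE,
                         ...))
    eta_mat <- do.call(rbind, lapply(fits, `[[`, "eta"))
    old_typ <- log(typical_vector(pop)[free_i])
    new_typ <- old_typ + colMeans(eta_mat)  # geometric mean of estimates
    om <- NULL
    if (est_omega)
      om <- stats::setNames(apply(eta_mat, 2, stats::sd), free_i)
    sig <- list(pk = NULL, anc = NULL, pc = NULL)
    if (update_sigma) {
      res <- do.call(rbind, lapply(fits, `[[`, "residuals"))
      res <- res[!res$bql, ]
      cc <- res[res$kind == "conc" & res$ipred > 0, ]
      if (nrow(cc)) sig$pk <- mean((cc$dv / cc$ipred - 1)^2)
      aa <- res[res$kind == "ANC", ]
      if (nrow(aa)) sig$anc <- mean(aa$res^2)
      pp <- res[res$kind == "PC", ]
      if (nrow(pp)) sig$pc <- mean(pp$res^2)
    }
    delta <- max(abs(new_typ - old_typ))
    pop <- pop_update(pop, typical = exp(new_typ), omega = om,
                      sigma2_pk_prop = sig$pk, sigma2_anc_add = sig$anc,
                      sigma2_pc_add = sig$pc)
    if (delta < tol) { converged <- TRUE; break }
  }
  structure(list(pop = pop, fits = fits, n_iter = it, converged = converged,
                 objective = sum(vapply(fits, `[[`, 0, "objective"))),
            class = "mt_pop_fit")
}

#' @export
print.mt_pop_fit <- function(x, ...) {
  cat(sprintf("<mt_pop_fit> %d subjects, %d iteration(s), %sconverged\n",
              length(x$fits), x$n_iter, if (x$converged) "" else "not "))
  print(x$pop)
  invisible(x)
}
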