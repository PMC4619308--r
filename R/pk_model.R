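#' Two-compartment (or one-compartment) disposition parameters
#'
#' Structural PK parameters on a per-m2 body-surface-area basis, as estimated
#' for decitabine: linear elimination from a central compartment with an
#' optional peripheral distribution compartment. Absolute clearances and
#' volumes for a subject are the per-m2 values multiplied by BSA; because
#' doses are likewise prescribed per m2, typical-subject concentration
#' profiles are BSA-invariant.
#'
#' @param cl clearance, L/h per m2
#' @param vc central volume of distribution, L per m2
#' @param vp peripheral volume, L per m2 (two-compartment only)
#' @param q intercompartmental clearance, L/h per m2 (two-compartment only)
#' @param n_compartments 1 or 2
#' @return an object of class `pk_parameters`
#' @examples
#' pk_parameters(cl = 87.8, vc = 18.5, vp = 22.9, q = 13.1)
#' @export
pk_parameters <- function(cl, vc, vp = NULL, q = NULL, n_compartments = 2) {
  n_compartments <- as.integer(n_compartments)
  if (!n_compartments %in% c(1L, 2L))
    stop_input("n_compartments must be 1 or 2")
  if (!is.finite(cl) || cl <= 0 || !is.finite(vc) || vc <= 0)
    stop_input("CL and Vc must be positive")
  if (n_compartments == 2L) {
    if (is.null(vp) || is.null(q) || !is.finite(vp) || vp <= 0 ||
        !is.finite(q) || q <= 0)
      stop_input("two-compartment model requires positive Vp and Q")
  } else {
    vp <- 0; q <- 0
  }
  structure(list(cl = cl, vc = vc, vp = vp, q = q,
                 n_compartments = n_compartments),
            class = "pk_parameters")
}

#' @export
print.pk_parameters <- function(x, ...) {
  cat(sprintf("<pk_parameters> %d-compartment: CL %.4g L/h/m2, Vc %.4g L/m2",
              x$n_compartments, x$cl, x$vc))
  if (x$n_compartments == 2L)
    cat(sprintf(", Vp %.4g L/m2, Q %.4g L/h/m2", x$vp, x$q))
  cat("\n")
  invisible(x)
}

#' Dosing regimen of timed intravenous infusions
#'
#' @param events data.frame with columns `start_time` (h since treatment
#'   initiation), `duration` (h), `dose_per_bsa` (mg/m2) and `bsa` (m2)
#' @param daily_dose,days_per_cycle,cycle_interval_days optional regimen
#'   metadata carried as attributes
#' @return an object of class `dose_regimen`
#' @export
dose_regimen <- function(events, daily_dose = NA_real_,
                         days_per_cycle = NA_integer_,
                         cycle_interval_days = NA_integer_) {
  need <- c("start_time", "duration", "dose_per_bsa", "bsa")
  if (!is.data.frame(events) || !all(need %in% names(events)))
    stop_input("events must be a data.frame with columns ",
               paste(need, collapse = ", "))
  if (nrow(events) > 0) {
    if (any(events$duration <= 0)) stop_input("infusion duration must be > 0")
    if (any(events$dose_per_bsa < 0)) stop_input("doses must be non-negative")
    if (any(events$bsa <= 0)) stop_input("BSA must be positive")
    events <- events[order(events$start_time), , drop = FALSE]
    rownames(events) <- NULL
  }
  structure(events, class = c("dose_regimen", "data.frame"),
            daily_dose = daily_dose, days_per_cycle = days_per_cycle,
            cycle_interval_days = cycle_interval_days)
}

#' Build the protocol's cyclic infusion regimen
#'
#' Daily 1-h intravenous infusions for `n_days` consecutive days, with cycles
#' repeated every `cycle_interval_days`. Defaults mirror the trial protocol
#' (5 consecutive days, 4-week intervals, 60-min infusions).
#'
#' @param daily_dose mg/m2/day
#' @param n_days dosing days per cycle
#' @param n_cycles number of cycles
#' @param cycle_interval_days days between cycle starts
#' @param infusion_hours infusion length in hours
#' @param bsa body surface area, m2
#' @param cycle_starts optional explicit cycle start times (h); overrides
#'   `cycle_interval_days`
#' @return a [dose_regimen()]
#' @export
standard_regimen <- function(daily_dose, n_days = 5, n_cycles = 1,
                             cycle_interval_days = 28, infusion_hours = 1,
                             bsa = 1, cycle_starts = NULL) {
  if (is.null(cycle_starts))
    cycle_starts <- (seq_len(n_cycles) - 1) * cycle_interval_days * 24
  starts <- as.vector(outer((seq_len(n_days) - 1) * 24, cycle_starts, `+`))
  ev <- data.frame(start_time = sort(starts), duration = infusion_hours,
                   dose_per_bsa = daily_dose, bsa = bsa)
  dose_regimen(ev, daily_dose = daily_dose, days_per_cycle = n_days,
               cycle_interval_days = cycle_interval_days)
}

# events as the (start, duration, rate ug/h) matrix used by the compiled core
events_matrix <- function(regimen) {
  if (nrow(regimen) == 0)
    return(matrix(numeric(0), 0, 3))
  rate <- regimen$dose_per_bsa * 1000 * regimen$bsa / regimen$duration
  cbind(regimen$start_time, regimen$duration, rate)
}

# packed parameter vector for the compiled core; absolute (BSA-scaled) values
pk_vec <- function(params, bsa = 1) {
  c(params$n_compartments, params$cl * bsa, params$vc * bsa,
    params$q * bsa, params$vp * bsa)
}

#' Predict plasma concentrations for an infusion regimen
#'
#' Closed-form solution of the linear one- or two-compartment disposition
#' model for zero-order infusions, superposed across all dose events. This
#' analytic path is the package's reference PK implementation; the compiled
#' ODE core reproduces it and is cross-checked in the test suite.
#'
#' @param params [pk_parameters()]
#' @param regimen [dose_regimen()]
#' @param times ascending, non-negative time grid (h)
#' @return numeric vector of concentrations (ng/mL)
#' @examples
#' pk <- pk_parameters(87.8, 18.5, 22.9, 13.1)
#' reg <- standard_regimen(5, n_days = 1)
#' predict_concentration(pk, reg, c(0, 0.5, 1, 2, 3))
#' @export
predict_concentration <- function(params, regimen, times) {
  check_times(times)
  ev <- events_matrix(regimen)
  bsa1 <- if (nrow(regimen)) regimen$bsa[1] else 1
  cl <- params$cl * bsa1; vc <- params$vc * bsa1
  conc <- numeric(length(times))
  if (nrow(ev) == 0) return(conc)
  if (params$n_compartments == 1L) {
    k <- cl / vc
    for (i in seq_len(nrow(ev))) {
      tau <- times - ev[i, 1]; dur <- ev[i, 2]; r <- ev[i, 3]
      during <- tau > 0 & tau <= dur
      after <- tau > dur
      conc[during] <- conc[during] + r / cl * (1 - exp(-k * tau[during]))
      conc[after] <- conc[after] +
        r / cl * (1 - exp(-k * dur)) * exp(-k * (tau[after] - dur))
    }
    return(conc)
  }
  mc <- macro_constants(params)
  a <- mc$alpha; b <- mc$beta
  k21 <- params$q / params$vp
  c1 <- (a - k21) / (a - b)
  c2 <- (k21 - b) / (a - b)
  for (i in seq_len(nrow(ev))) {
    tau <- times - ev[i, 1]; dur <- ev[i, 2]; r <- ev[i, 3]
    during <- tau > 0 & tau <= dur
    after <- tau > dur
    conc[during] <- conc[during] + r / vc *
      (c1 * (1 - exp(-a * tau[during])) / a +
       c2 * (1 - exp(-b * tau[during])) / b)
    tp <- tau[after] - dur
    conc[after] <- conc[after] + r / vc *
      (c1 * (1 - exp(-a * dur)) * exp(-a * tp) / a +
       c2 * (1 - exp(-b * dur)) * exp(-b * tp) / b)
  }
  conc
}

#' Disposition exponents and half-lives
#'
#' The distribution (`alpha`) and terminal (`beta`) exponents of the
#' two-compartment model, i.e. the roots of the characteristic quadratic
#' \eqn{\lambda^2 - (k10+k12+k21)\lambda + k10\,k21 = 0}, with the
#' corresponding half-lives. For a one-compartment model the single
#' elimination rate constant CL/Vc and its half-life are returned.
#'
#' @param params [pk_parameters()]
#' @return named list: `alpha`, `beta`, `half_life_alpha`, `half_life_beta`
#'   (two-compartment) or `k`, `half_life` (one-compartment)
#' @export
macro_constants <- function(params) {
  if (params$n_compartments == 1L) {
    k <- params$cl / params$vc
    return(list(k = k, half_life = log(2) / k))
  }
  k10 <- params$cl / params$vc
  k12 <- params$q / params$vc
  k21 <- params$q / params$vp
  s <- k10 + k12 + k21
  disc <- sqrt(max(s^2 - 4 * k10 * k21, 0))
  alpha <- (s + disc) / 2
  beta <- (s - disc) / 2
  list(alpha = alpha, beta = beta,
       half_life_alpha = log(2) / alpha, half_life_beta = log(2) / beta)
}

#' Area under the concentration curve per treatment cycle
#'
#' For linear disposition the total AUC equals total administered dose
#' divided by clearance, independent of the infusion schedule; this is used
#' as a linearity check on the closed-form solution.
#'
#' @param params [pk_parameters()]
#' @param regimen [dose_regimen()]
#' @return AUC in ng.h/mL per cycle (BSA-invariant)
#' @export
auc_per_cycle <- function(params, regimen) {
  n_cycles <- 1
  if (nrow(regimen) && !is.na(attr(regimen, "days_per_cycle")))
    n_cycles <- max(1, nrow(regimen) / attr(regimen, "days_per_cycle"))
  sum(regimen$dose_per_bsa) * 1000 / params$cl / n_cycles
}
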