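#' Transit-compartment myelosuppression parameters
#'
#' Parameters of the five-compartment transit model with feedback used for
#' both toxicity markers: a proliferating pool A1 feeding a chain of three
#' transit compartments into the circulating pool A5, with production
#' inhibited linearly by drug concentration and stimulated by the feedback
#' term (BASE/A5)^GAMMA when circulating counts fall below baseline. For
#' platelets the fixed baseline is replaced by an asymptotically increasing
#' target `BASE + IMP (1 - exp(-IMK t))` describing gradual post-transplant
#' recovery of the platelet baseline over treatment.
#'
#' @param ktr transit rate constant, 1/h
#' @param slope linear drug-effect coefficient, mL/ng
#' @param base baseline circulating count, cells/mm3
#' @param gamma feedback exponent (dimensionless)
#' @param imp maximum asymptotic baseline recovery, cells/mm3 (platelets only)
#' @param imk asymptotic recovery rate constant, 1/h (platelets only)
#' @param marker `"ANC"` or `"PC"`; the neutrophil marker forces
#'   `imp = imk = 0`
#' @return an object of class `pd_parameters`
#' @examples
#' pd_parameters(0.0132, 0.263, 3240, 0.193, marker = "ANC")
#' @export
pd_parameters <- function(ktr, slope, base, gamma, imp = 0, imk = 0,
                          marker = c("ANC", "PC")) {
  marker <- match.arg(marker)
  if (!is.finite(ktr) || ktr <= 0) stop_input("ktr must be positive")
  if (!is.finite(base) || base <= 0) stop_input("BASE must be positive")
  if (slope < 0 || gamma < 0 || imp < 0 || imk < 0)
    stop_input("SLOPE, GAMMA, IMP, IMK must be non-negative")
  if (marker == "ANC" && (imp != 0 || imk != 0))
    stop_input("the ANC marker has no asymptotic baseline (IMP = IMK = 0)")
  structure(list(ktr = ktr, slope = slope, base = base, gamma = gamma,
                 imp = imp, imk = imk, marker = marker),
            class = "pd_parameters")
}

#' @export
print.pd_parameters <- function(x, ...) {
  cat(sprintf(
    "<pd_parameters> %s: ktr %.4g /h, SLOPE %.4g mL/ng, BASE %.4g /mm3, GAMMA %.4g",
    x$marker, x$ktr, x$slope, x$base, x$gamma))
  if (x$imp > 0) cat(sprintf(", IMP %.4g, IMK %.4g /h", x$imp, x$imk))
  cat("\n")
  invisible(x)
}

pd_vec <- function(params) {
  c(params$ktr, params$slope, params$base, params$gamma, params$imp,
    params$imk)
}

#' Time-varying baseline target
#'
#' `BASE + IMP (1 - exp(-IMK t))` where `t` is time since treatment
#' initiation; reduces to the constant `BASE` when `IMP = 0` (neutrophils).
#'
#' @param params [pd_parameters()]
#' @param t time since first dose, h (non-negative)
#' @return baseline count, cells/mm3
#' @export
baseline_at <- function(params, t) {
  if (any(t < 0)) stop_input("t must be non-negative")
  params$base + params$imp * (1 - exp(-params$imk * t))
}

#' Right-hand side of the transit-feedback system
#'
#' Exact algebraic form, with no regularisation: the production term may go
#' negative when SLOPE.C exceeds 1 (net cell kill exceeding production), as
#' the linear drug-effect model implies at high concentrations.
#'
#' @param state numeric length-5 vector (A1 proliferating, A2-A4 transit,
#'   A5 circulating), all strictly positive
#' @param t time since first dose, h
#' @param params [pd_parameters()]
#' @param conc drug concentration, ng/mL
#' @return numeric length-5 vector of derivatives, cells/mm3/h
#' @export
pd_derivatives <- function(state, t, params, conc) {
  if (length(state) != 5) stop_input("state must have 5 compartments")
  if (state[5] <= 0) stop("circulating compartment must be positive")
  b <- baseline_at(params, t)
  fb <- if (params$gamma == 0) 1 else (b / state[5])^params$gamma
  d1 <- params$ktr * state[1] * ((1 - params$slope * conc) * fb - 1)
  c(d1, params$ktr * (state[1:4] - state[2:5]))
}

#' Simulate a blood-cell-count trajectory under a dosing regimen
#'
#' Integrates the transit-feedback system coupled to the closed-form PK
#' solution (the drug concentration enters analytically, so only the five
#' cell compartments are integrated). All compartments are initialised at
#' BASE at t = 0. For platelets the time-varying baseline target makes the
#' zero-dose system non-stationary by construction: counts drift upward
#' towards BASE + IMP.
#'
#' @param pd [pd_parameters()]
#' @param pk [pk_parameters()]
#' @param regimen [dose_regimen()]
#' @param grid ascending time grid starting at 0 (h)
#' @param rtol,atol integration tolerances (relative; absolute in cells/mm3)
#' @param full_state return the full 5-compartment state matrix as well
#' @return an `mt_trajectory`: list with `times`, `values` (circulating
#'   counts, cells/mm3), `marker`, and optionally `state`
#' @examples
#' pk <- pk_parameters(87.8, 18.5, 22.9, 13.1)
#' anc <- pd_parameters(0.0132, 0.263, 3240, 0.193, marker = "ANC")
#' traj <- simulate_marker(anc, pk, standard_regimen(5), seq(0, 1344, by = 24))
#' find_nadir(traj)
#' @export
simulate_marker <- function(pd, pk, regimen, grid, rtol = 1e-8, atol = 1e-6,
                            full_state = FALSE) {
  check_times(grid, require_zero_start = TRUE)
  bsa <- if (nrow(regimen)) regimen$bsa[1] else 1
  st <- cpp_simulate(grid, events_matrix(regimen), pk_vec(pk, bsa),
                     matrix(pd_vec(pd), 1, 6), rep(pd$base, 5), rtol, atol)
  structure(list(times = grid, values = st[, 5], marker = pd$marker,
                 state = if (full_state) st else NULL),
            class = "mt_trajectory")
}

#' @export
print.mt_trajectory <- function(x, ...) {
  cat(sprintf("<mt_trajectory> %s, %d points over %.1f h (min %.4g /mm3)\n",
              x$marker, length(x$times), max(x$times), min(x$values)))
  invisible(x)
}

#' @export
plot.mt_trajectory <- function(x, ...) {
  plot(x$times / 168, x$values, type = "l", xlab = "weeks since first dose",
       ylab = sprintf("%s (/mm3)", x$marker), ...)
  invisible(x)
}

#' @export
as.data.frame.mt_trajectory <- function(x, ...) {
  data.frame(marker = x$marker, time_h = x$times, value = x$values)
}

#' Locate the nadir of a trajectory
#'
#' Global minimum of the circulating count over a time window, ties broken
#' by the earliest time, refined by a local quadratic fit through the grid
#' point and its neighbours.
#'
#' @param traj an `mt_trajectory` (or list with `times`/`values`)
#' @param window length-2 numeric, h; defaults to the full trajectory span
#' @return list with `time` (h) and `value` (cells/mm3)
#' @export
find_nadir <- function(traj, window = NULL) {
  window <- window %||% range(traj$times)
  keep <- traj$times >= window[1] & traj$times <= window[2]
  if (!any(keep)) stop_input("empty nadir window")
  tt <- traj$times[keep]; vv <- traj$values[keep]
  i <- which.min(vv)  # earliest index on ties
  tmin <- tt[i]; vmin <- vv[i]
  if (i > 1 && i < length(vv)) {
    t0 <- tt[i - 1]; t1 <- tt[i]; t2 <- tt[i + 1]
    y0 <- vv[i - 1]; y1 <- vv[i]; y2 <- vv[i + 1]
    d1 <- (y1 - y0) / (t1 - t0); d2 <- (y2 - y1) / (t2 - t1)
    c2 <- (d2 - d1) / (t2 - t0)
    if (c2 > 0) {
      tv <- (t0 + t1) / 2 - d1 / (2 * c2)
      if (tv > t0 && tv < t2 && tv >= window[1]) {
        yv <- y0 + d1 * (tv - t0) + c2 * (tv - t0) * (tv - t1)
        if (yv < vmin) { tmin <- tv; vmin <- yv }
      }
    }
  }
  list(time = tmin, value = vmin)
}
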